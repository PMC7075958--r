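>KV72_SYNTHETIC synthetic Kv7.2-like
MICTWGFPFWPQNMYGPFEMFVWRTNVFLMGECTVMWHTVNVPNLKYTDCHFHPQNCPWM
THPCTDYVGGLEANAREISPAATRAAIVNPLDCCGNVGLTWLNFSQCLPTNLSRIYPWCN
RSRAPNPWMADNEELIFSFSPLHKICQMLQGFSEMVHFHVPTTFGGVMSQANYKCLLANH
NYLDYDDATTDPYYSNCVSYDIFWMNEWCENWRGHCARNHKHYCYKDLYSMCGYRFMVLD
DIQEKQLACWVPETSMIFFSMYCFSKFKLSEIQAMVDFNCVMSFLQSDLYQLKAFFSVAL
THEHSAIHPHEMVFFAEEVAMCDWWNQFEPYILIVTHDMPLPSITVKLGPSPEWGFHFNE
SNVKCGPWSAAMPALIVIHNIRYEIKIAATGMSLKQAGAPMYTVSETCPDMVRIDKDVYR
NRTTQIKEFLWNRQLWFPCDFTNPLPPLLPAFEMCTIPHQYFNSPQLFYGKQVSIGGEAF
SEECTIDHFMNKHACVFHQYNLCYPSIWCLPYIEPWRDFFTKWPFIEAVIKKCDSSYSSG
NLIENAYTMPRMASDFNRMIYGIQQCASWGLFRRGHHDWMIHMPNEHYSRYQHTGHTTPD
ICWAGNFSECAISHPMTIAKMRAGIPQQGSSVPVQRELDHAATWPILSQGNSEAYEMFNE
QDTWNCGELWIDCSVILRSLTNHEAAIRRTYWSYQCFYSCSFIYQNFFPMPGYVWVLWTF
QADKSEEIRNAYPQPNKCSKHKTLKYLICLDYSQWQIKNPFCCAQVPLYPPPEIMTWRDD
SWKKQWPHTGACHNFMFIGGDYPMTDCCSVVSSFSISRAKMFQYYKWPGHWWHQSDFNRE
TQLNDPGINGQDDLVQMINNLGYDEGPFLDVW
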