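>FOLH1_SYNTHETIC synthetic FOLH1 stand-in reference (pocket residues planted at canonical positions)
MGWTVGEGSMWRVKWSREITGMGYHPEGYRIPKTYSTQTKGFNTMEYKQNPKTFIIGNRI
NSTWNAGNARPQGPPLVVTEHCHSWTGLSNSTWGGPPRIPDGWVKFDSIWNSNHITERRN
VIPQKQYQMCHDHQVVYITYQMSPQTGDYHTWSQATSVHVLIHSIGQSLSGDWYIRNCEE
SNLMIHNSENYVQTILKGMLCSYPCDHQPRWAQVRHDKSNFNFPMPNQCIYVLNFIRQQW
WTYVAPTQHYMLTNPENNNKKPIINPHLVVRRDIKYDPLETMIYSMCKFKMSHLEKRMMM
RQNLWPSTKISPFHQKHKCMAQYFNWDAKMEHHMKEFRFEGICNHLYQHPCLLKSFFLHW
EVTKLALGLYTIDNVHHPNWGNIQWPDFYRFWFAELSDYGYVVPYTQCLHYGMKQIVQLA
IFCEEEDKICCKIHVQQSVEHFEPQPLSNGMWDQNDKCAQEYRRMIYDMCQIQEYLGQHL
AAMLNWTVCHMLLWTSMWWYRPVNSICMHNDHPLNMNGNQYISHDSHDGWVYRRLRDWSP
WYMEFYLGPPFYHCNESSECVASHEGCGSHKFCWQVMWGDQRMPKHWTAPAHRQHTVYIK
CLQQTGPSWYAPQYYNLPMVSNNGYMRNAMIVSPPVWQGMATYYCHSDGCAVESMLPNRI
QWCCPHEPMVSFTSCTFFCVTAEGDMTQHPHVEICDCLKYSCTGEDKFGVVMFDEKVSLW
PVPYTSPWFLRRDKFKKASCIHRNNFSFGV
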