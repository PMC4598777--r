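"kind","symbol","monoisotopic","average","formula"
"element","C",12,12.011,"C"
"element","H",1.007825,1.008,"H"
"element","N",14.003074,14.007,"N"
"element","O",15.9949146,15.999,"O"
"element","S",31.9720707,32.06,"S"
"aa_residue","A",71.0371136,71.079,"C3H5N1O1"
"aa_residue","R",156.1011106,156.189,"C6H12N4O1"
"aa_residue","N",114.0429272,114.104,"C4H6N2O2"
"aa_residue","D",115.0269428,115.088,"C4H5N1O3"
"aa_residue","C",103.0091843,103.139,"C3H5N1O1S1"
"aa_residue","E",129.0425928,129.115,"C5H7N1O3"
"aa_residue","Q",128.0585772,128.131,"C5H8N2O2"
"aa_residue","G",57.0214636,57.052,"C2H3N1O1"
"aa_residue","H",137.0589116,137.142,"C6H7N3O1"
"aa_residue","I",113.0840636,113.16,"C6H11N1O1"
"aa_residue","L",113.0840636,113.16,"C6H11N1O1"
"aa_residue","K",128.0949626,128.175,"C6H12N2O1"
"aa_residue","M",131.0404843,131.193,"C5H9N1O1S1"
"aa_residue","F",147.0684136,147.177,"C9H9N1O1"
"aa_residue","P",97.0527636,97.117,"C5H7N1O1"
"aa_residue","S",87.0320282,87.078,"C3H5N1O2"
"aa_residue","T",101.0476782,101.105,"C4H7N1O2"
"aa_residue","W",186.0793126,186.214,"C11H10N2O1"
"aa_residue","Y",163.0633282,163.176,"C9H9N1O2"
"aa_residue","V",99.0684136,99.133,"C5H9N1O1"
"glycan_residue","hex",162.052823,162.141,"C6H10O5"
"glycan_residue","hexnac",203.079372,203.194,"C8H13N1O5"
"glycan_residue","dhex",146.0579084,146.142,"C6H10O4"
"glycan_residue","neuac",291.0954158,291.256,"C11H17N1O8"
"constant","water",18.0105646,18.015,"H2O1"
"constant","proton",1.007276,1.007276,"p"
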