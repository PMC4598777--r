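>CTSG_SYN synthetic stand-in, cathepsin G-like precursor; unprocessed numbering; mature chain 21-243/244; glycosite Asn71
HAVGDGRDRHKVDQVDHGKHKGKVQQHDERAEHAMRHKQAVCDGEAGHQYRDKGRRVCAE
KHVHRFGSNINVTLVRDQDLHQAQDVADDVQGRAFAHVEGVHQDQVDDRMRHVEHQRKDA
AERKLQEREAGGKVVCGKQFHDDDHAGKHVVMRQGRHDVVRHQHLDRERAVHEGDQAYED
VCDHQRDGRLHQGCAHEGQASDHDHKGNGFDVAHRHEGHVDLVDCKEKAYEVVARGLIRT
TMRSFQPGAEAGAHD
>AZU1_SYN synthetic stand-in, azurocidin-like chain; glycosites Asn126, Asn171
GAEGDHDDRAAEQVAVQEGKEQERACGDRYERERQEAVKQAHGHLEQVEGRKEGCGEEEF
VQQHHHDGDHAHVGLDQQVDGAHGGGQHHYKDKADEAQVCVQGKLREAHVVGDQDHGLGK
GQKAQNATKRFHEKDDKRARHGVVFGHAQCEAGVLGHAKVQDVLKGHHGANGSEHDVFGD
GDQDDRGGRYRVHKERVVGCAKGGLAEGDEEEDKGEAHHFKHEAVAADVRDHRQLEKHRC
RVEKYREREKA
>ELANE_SYN synthetic stand-in, neutrophil elastase-like chain; glycosites Asn124, Asn173
RKVVERQGVRGKRQRKHQEKEADKVAGYHQACADEQVRVDEHVLHAQEVKRDDDVRRAVR
HFGVVVEGACDEHDGHDLKEKERRVEKDQRQVKEYQDDVHRDQHEVQLAHAAQQQLHVRH
HGGNVTGHGFQGQVCRAQVHQFVQAQEGERHKVAKLKDDCVKRKHLGVQVHQNASDHKRF
AKGKAGADARQYQKRAVRQRQVERAKHHRLDGDDCDGGHRRQERFEHAEHDRKAQKGVHL
QRQDQAKKKCDHQGYREDRQEQEARDQ
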