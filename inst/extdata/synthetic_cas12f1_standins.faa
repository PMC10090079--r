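>OsCas12f1_synthetic_standin synthetic stand-in, 433 aa, D228/D406 planted (not the published sequence)
MFQIPTVCCTNINGANWEACGHIMHPCTMPEAMSHFPTFNFCCGSKYFMYNIKKNFMSGHRRKLVQMREG
PHVRIIPMMYIYTCNMLAEWCWGIYPEYCFYHHSEAGEPAFGYGAWTTRSFLRFVRSRPGTQNCWISVRK
GFLWQKNQPEVVSKFVKPPCAYAYWKIEYYHLSFLGFFRLMWKSWRNPGMNFNCCCKWRMPQTFLLSHFT
RLKTWWTYLMRCQYMRHDRGFWFHAVLVLWPRNHFSQVEQREVFEMAVKVRHMLRNFRFLKWCTRCPNLY
PPSCVYQRTNQRLGYQFQRQMTRLCGFLFAGKVGTLCFHMQVHLGFRYGYMYSWHCMRSFRASHFNQEGP
AYHWFYMYNVSYATHNQMIEKTCTQCSQSLPLQLYGESYLMRCQECQCTWTGIKIDKYLINVFEICPGAC
LHEGKKSPPHHTA
>RhCas12f1_synthetic_standin synthetic stand-in, 415 aa, D210/D388 planted (not the published sequence)
MRVEHYIMTGFSYNVNWIWIKTVSTVKQGLYYGNHFPTKHGFWKRQFCISHWVLCFCSRCWWKFMAHPFT
KLQHCVFCRWLFMWSKHSCIRNCNNNMNWMAWNMVQACKYIRGLKYLNKSVRPRQWYKVGKKMPAHFISF
VFIKQNWHPPRRHGNEFFSSISEQAWYMVYYLQAWPPEMLTNVTAIHCKFLVMSCALCANYGYNVCVEWD
SWQCVQIPMGCEGPGGMFKSHVCWQQFAIRIYSHYGENSMLYPYWGGCWPESSNIGRTFSRPNSKHRTMC
KQEEGKPTLYFTWALMMSEYKFFLGNWNGRAAQCSPGRRMMGYSFSIHKSFVNCIHAQYQEYMKYTTNSM
FRGNCNFCRVSCEIYHEEVRAIACCRHCAEFVFFQWYDCYANKINYGYEYPIHFFVHMIFITIYA
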