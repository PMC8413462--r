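>synthetic_L7Ae synthetic stand-in (protein, sized to the documented component mass; not the natural sequence)
SLMDKQRWGMSHLTDTRAGWAHCWDRYYHMCPDIFVKWEPYHFWAAISKELMIIQEQHMD
TWYELTCYAGPKTPSGLWPTTELARARPYHLGCRECPGVSRFGNGIIRLSWYR
>synthetic_Nop5 synthetic stand-in (protein, sized to the documented component mass; not the natural sequence)
TQVMAVLPVMQKNKYVSLQSENHVEVAQIDYMQGHKVSNNLWRFHRDPVNPWSQFFYPMF
PHMCHNYAIFWVCFPNERPEQVIWIMMEHDALVDKMMGLKECRVHRGTGCIYWEVTVKPF
CNMEGYMLKAQPKVYWNCKYELWKNQLFLEVKNCQTQGNAILRQNCYQGPMDENIGTPFT
KKRTCLNDEQNKWKFYHLRAMGFFVYLSNYLEMHSDQLHGCRPGMFEHHNGVDRAYFKTY
VFYRMKFQCSDRCVAVFEYALPHPPCPEISHDLPHTNMVLTDIWHHPDFAFTFPPGPFDE
EEWQGVVLDWSRNCAQMAKQDHPNCGGFHTDATPPQIEDHFLWHCFPGNYFDFYDPNFEA
HAKMDDDIVQIYQMGANPQWKCYSNQGRLNIYTC
>synthetic_Fib synthetic stand-in (protein, sized to the documented component mass; not the natural sequence)
NSKLISLRTRSYSLARGKAIQRKISIEPWFDARILPFPCEPRDQMVDICMSEGMHMRYDV
CSRFWYEHDYYENPWEKHPRKLEHESENQEYDTQTKCSRAITLKSGLRKSWAIHAGAGWM
GGHCPWLQYCLYDVTGIKFPFHSQWSPKMFHARDEEWPTNHEDPICNTLCNQMQGTAAYQ
YNHELINMGDFMDFWQRVGWPLNSQGWECTYQQIQAA
>synthetic_Snu13 synthetic stand-in (protein, sized to the documented component mass; not the natural sequence)
DNCVSVAPNYVGKNQYGKAHNWEWHGPPHWWALATATWYSGHIWQTCNITFFAKIFKTMQ
VADCFENACKFETNICSEWQPWHVNVLLRLGSGWVWNIMKTQFLFQWEWNDHCS
>synthetic_snR51 synthetic stand-in (rna, sized to the documented component mass; not the natural sequence)
GGCUGUGUGUGAGUCAGUAGUGGCGAGGUCCCAUCCUUACACCGGCAGUGGAACACCGUC
AAGUGUGUAGUUGUUGCUAAUUUACCCUUCCUUCGUAGCGGCCCUAGA
>synthetic_sR26 synthetic stand-in (rna, sized to the documented component mass; not the natural sequence)
GCUACGGCUUCCGUGCAGCGGGGUCCGCCGCGCGUCGCUGUGGCGGUGAGCAUUCGAUUG
AGAC
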