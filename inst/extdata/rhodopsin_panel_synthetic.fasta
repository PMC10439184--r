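>AAG10475.1
PDKPYVSRAKSKAWEAACLHKAGSHCSWFRPPPIVINIRNKSRVRFHVGEDTGPGNDAAETGDIDKPRKLHRVGLFVFET
QEEGKVTSVVNPITAVGADWTYYELKNNMIFALIWSSQMVWMCEVAVFRAAVWMLGNDQMQSYMCPDQDEYLMFLQNMDK
TDVTVDAFPVPQEKQISIGMALKIGSWSILITLKQEKFQGSDTSISFRPVQAMMFVASTHFSMMWIGMIEAYNREHGGRS
VENGDNFKR
>AAK30179.1
PVKQYVSRIKSKAHEAACLHKAGSHHSWARPRPPRINIRNKSRVRFHVGEDPGPGNDAAESGDIDKPRKLHSVGEFVFET
QEKSKVHSVVMPITAVGADWTYYEQKNSMIFDLIWSPQCYEMQEVAGFRQAVHMLGNDQMYSYCCPDVREWLMFLQNFDK
TGVTVDAKPVPQIKQLRMGMILNEGAWSILIKVKLEKFQKSDTRIHFRGVDAMSFVATGSASMMWIEIIEYYYSEHGGLS
VRNTDNQKR
>BAN14807.1
PDVMYVSRAKSKGHEQACLHKAGSHHSWVRPRPPVNNIRNKSRVRFHGNDDTGPENDAAESGDIIKPKKYHRRMLFVFGT
QESNKVTSVVMPITAVGADWQYYEMKNNMIFALITSPQCVEMCEVTVFRAAVWMLGNVQMQSYCCPDVALWLMFLQNCDK
TGVTVDAKPAPQEKQISIGMALKFKAFSIYITLTLEKFQGSDTQISFRGVDAMSFVASTSFSMMWIGIIEYYYRECSGLS
VEETDNFKR
>AAZ21446.1
PDKPYVSRAKSKAHEAACLHKAGSHHSWARPRPPVINIRNNSRVRFHVQEDIGPGNDVAGSGDHDHPRKLHRVGAFVGET
QESSKVDSVGMPITAVGADWQYYEQRNGMLFAAIWSPQCVEMCESAVGRAGVWMLGNDQMQSNCCPDVAHWLMFEQACDK
TGVTVDAKPNDQEKQISWGMASKEGAWSILITTELEKFQGERYRIFFRGVDAMSFVAPTSYSMMVIGIIEYVYREHGGLS
VENTDNMKR
>PR_KMIC_SYN
PDKPYYSRYKSYQHEAACLTKAESKHEWARFRPLVRQIRNKVRVRFHVGEITGMYNDAAESGSIDFVRKLCRVYLFEFET
QASCPVDSSVMAMTAVGFQWCYYEMKKMMLFAYIWSPQCVLMHEVACKRAAYWMPKNDQMQSYCCPDVAEWLMDQQNCDN
TCTTVDQQPVPQEKQIPRGMAPKEFAWSLLITLKLEKFGGSDCRISGWGVRAMSFVASTSFSMMWIGIISWYYREHGGLW
HENTDNFER
>PR_CFUS_SYN
PDKLYYSRYKSQQHEAACLTKAGSKHEWARPRPLVRQIRNNVRVIFHVGEDTGMYNDAGESGSIDKVRKLCRVGLREFET
PASSPVDSVVMPMTFVGADWCYYEMKKMMLFAYIWDPMCVLMREYACKRAAVWMLKNLYMQSYCNPDVAEWLMFQQNCDN
TCTTVDQKPVPDEKQFSRGMAPKEGFWSLLITLKLEKFGGSDCRISGWGVRAMSMVASTSFSMMWIGIIWWYYREHGGLV
VENTDNFEC
>PR_AAND_SYN
PDDPYYSRYKSYQHEAACLTKAGSKHEWARPRPCVRQIRNKVRVRFHVGEDTGMYNDAAESGSIDKVRKLCRVGLFEFET
QASSPVQSVVMPMTAVGADWCYYELKKMMLFAYIWSVQCVIMRPVACIRAAVWMLKNDAMQSYCCPEVAEWLMFQENCDN
TCTTVDQKPVPQEKQISRGMAPKWGAWSLLITLKLEKFGGSDCRISGWGVRMMSFVVSTSFSMMWIGIIEWYYREHGGLW
HENTDNFER
>AIN36550.1
MKKEMVCHCRDKTETMSLSRYAGLFIWTFFSREPVCNQMGWCQVRGQVGKDYHLVHFFAMKFMDDKFCTLHRSGCNVFGT
LVAEDWDEHWLPIDVHICRTHTYADHCNDIGVDVKSEYMVSNPSIESGMAQVRTHQNDQIQMLQCWPDKNWGTFLQWLEA
LERTFDANPYMAEICMVIGVALSESGGTCHIMLVNCYFPGNLLQPTGQYFQYSFFMARQWYSFEHIAKAFYQYVVLGGPV
QCKVDNCKR
>ADY17811.1
MKGEMVCHCRDKTPTMELSAYAGLIIPTFFFPEPVCNITGWSGVRVQVGADYHLVHFFAMKFMFDKVRTLIRLGCNVPGT
LVATCWDEGWLPIDQMIARTKTLADTCNDIGVLVKGEDSVSNPSIEEGNAQVRTHCNDQIQSLQCRPDKNWVTFLQWLEA
LERTFDANPYMAEICIVIGVALSESGGYCLIMLVNCYFKYNLAQPAGQYQQYNFFMARQSYSFMYIRKAFYQYVVLGGPM
QCTVDNCKR
>ABV22426.1
MKKEMVCQCVDDTRTMSLSAYAGLFIPTFFFREPVCNWTGWSGVRGQFGKDYHLVHFFAMKFMDDKFRTLIRLGCNVTGT
LVAECWDEHWLYIGQMIARTKYYDDTCNDIGVLVKSEYSVANISIEAFMEQVRTHCNDQIQSLQCRPCKNWGTFLQWLEA
LERTFDDDPYMAQTCIVISVALSECGGYCIIMWVPCDFKGNLLQPAGQYQWYCVFMARQSYSFMHIRKAIYQYVVHGGPV
QCFVDNCKR
>AAO14677.1
LKKEMPCEKDDKTFTMSLSAYAGLFIITFFFREPVCNITGWSGVRGQVGADYHLVVFKSMKFMDDKDTTLIRLGCNVFGT
LCAECWKEHKLPIDQMCARTKTYADGCNDIGVLVKSVYSVSNPSIEMGMAMVRTHCNDQIQSLQCRPDKNWGTFLQWLEA
LERTFDANPYMDEICIVSGVYLSESGGYCLSMLVNMYIKGNLLQPAHQYQQYCFFMAAQSYSFMHQRKIFYQYVVNGGPV
QCTVDNCKR
>BAC88139.1
SEGRCVLHCRKKARSMSLSCYAGSMIPTFFFREPWCGITGWSGVRGQVGKDYILVHFFWMKFMDTKFRTLIRLFCNCFGT
LVAGSVCEHWLPIDMAHARTKTYADGANDIGVLVKSEGSVSNHSIPMVMAQVQTNCNDQDQSLQCRPNRNLITFMQWLEH
LEETGICNPYTAENCIVIDMAVSENEGRALIMLVNMYFKGNWLSQAQQSQQYNFRMDLHSYSFMHIQEAFYTYVVLGPPV
QCTVDNRKR
>BR_HALSAL_SYN
MWVPYQSGVLEIAFVAQLNWKHGCRIWLAEPRVPGINCNQMCSPRGIVGERAVLVWYRAPHRAGDKYWTAALLLMFSCET
FAREKFDSHYMPIIITAALAVTYADKNQRFWALHAWPEYVVKKEAHVQGEYVNVCCNGQIQSMLCWDIFEEDTYLNNLDY
LDNTFDAIKVLRTWAVSYPIISGICITRIYIRYKIEFHLYRSLMSNVQKIDGIFFVKRDSYLMGASNFHFYSYRGLDGMK
DVLVQRGGRLVLFAVWFVFEAG
>SRI_HALSAL_SYN
MWHNAQSDNIGTYFVWQHNWKHGCHIWLARPREPMINCNQMCSPHGLVTYRSVHVWIVKPHRYGGKYEEAAALHMFSART
FAYEKHDGHYMIIIITHTTAVTILDKNQRFWQLEAWPVYVVTIEAHVQIKYVVVICYGGIQSVLCLDIFSWDGVLNPLLY
QDNTFDASETYHTWTASSSPFAGSWITRTYTEYVLLFHVYRSLRPSVQKIDRGFFDRRDPYCMMAREHHFIQYRGSDGMS
DWKVQFMAM
>SRII_HALVAL_SYN
MWYKAQSDVTETQLVWQHNWKHGCIIWLRRPWEPMWDCVQICHPHGLVALISVHVTSVKPHRYIGKYWTAKALHMFSART
FAIHKHFEKYYSIIITHTTAWGICDKNQRFWGLEKWPVCFVEKEAHAQDKYVVVCCYQGIQSVLCHDIVSWDWVLFRSDY
LQNTFIASETYHTWIATYSIFCGSQITRTKTEYILLFHVYRGLRPSVQKIDRIFFFPRTPYCMMAFEHHTNQYRGSDGMN
DRHVNRMAM
>VIRR_OLV1_SYN
PAKPLMTGWEDKARDKREMMHARSPIILFDPRPTGMPMNNKSRVWLLENEFTQTVTFGSHVRMLQKARRCAALKDFLFEG
LVAQNPDDHSWPTIILFAGVYTDITRENMIFILHCQWHKVECGICAVLMWHVRTHGNKWIFPMDPPLIAIRLDFTEYLPQ
LERTLDYSFPPNEKAGWIGVALGNHATYALKEWTIEYYMGADPRSNCRDSDYMLFVWSPSYSMMAPHHIFYVNRCFIGLE
QERVKYFKR
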