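LOCUS       GCA_SYN0003__1_glim 3915 bp    DNA     linear   UNK
DEFINITION  GCA_SYN0003__1_glim contig=ctg1 start=0 end=3915.
FEATURES             Location/Qualifiers
     CDS             complement(1..1146)
                     /locus_tag="GCA_SYN0003__1_glim_g1"
                     /product="bacteriocin signature gene"
                     /translation="MFCQGHIGARMHGIMAMYIGSTDIHMYGGWFSSSMYDDICKDLM
                     RTFQLAIKMTGGTTVREMLSNESLPVAWKCGVIWTTAFHYTRKNSVKVYHRQWQMSYL
                     GVYNKWGRVPSKMPIDCPIPLMHFGTEWVENKQFDPMEVERWLVLISEPDKCMCVVFA
                     ICFNLLCDPSHDNADLYDWNMDWTKPYWNHVVMAAEDYKKWHDMFMFTEEEWKRCLMD
                     KTISHGKQQWAMGARFTAAVQKNFCRWMLLKAHDRLGTGPDYVTEPKCNSVVFPLLCL
                     WYFEMDQSCHQKTINQRNSPPKTREGSINKLCVNHWKCFLNFSYAEVRQCWEFDMAVG
                     YVEIHECPHNRTQYMYSLMHCNFLETNWIFFFHCTAPSWSESSGHDTI"
     CDS             complement(1983..2681)
                     /locus_tag="GCA_SYN0003__1_glim_g2"
                     /product="hypothetical protein"
                     /translation="TQLLMCGRCVRTSDTVIATLSFSINPEQKVIYNIHAFMMYYSNS
                     EREEEVIWDLFWPIRALDRRFVHPGAYHIEYWNPDSMFVTWLKRDYTDDIFHILCHAG
                     DLCNVCGPFWMNSNVHLIGVFGNSHHSAFNEGCDHTTCLSLTMGMIFCSFKHSRMVMY
                     VCKDATNWDCSHYHRRVGKIDNGFVSRPDPWPGCTKAEQVFSQFYASFTAIPVLDVIG
                     RQANMAPMPVFRWDF"
     CDS             3118..3915
                     /locus_tag="GCA_SYN0003__1_glim_g3"
                     /product="hypothetical protein"
                     /translation="VGMDCKTDFSYCDALESHKTAMQRCPDGYDHEARMPLWIIDCWM
                     VWYYVNVIFFMALNFILCVYTEGGSWAQEGVSVLSANESDFLDHDMTCYFVNRSHEVC
                     KRKWEVQVWTLSTQALKENVNQSYWIRKYVWLYVTCQGMWQGDASMCKPWWKWAYGGI
                     VCFLQFYFEDVCWCNITVIYDEIGPDMFQPGGCKQMHDDIGHWMPYMQVYPSYGWMVK
                     WWQEAEWCCFPRGYELGPGHSTVCQTFSAHECWFPADDVLFHDLAFSE"
ORIGIN
//
LOCUS       GCA_SYN0003__2_glim 4727 bp    DNA     linear   UNK
DEFINITION  GCA_SYN0003__2_glim contig=ctg1 start=2003915 end=2008642.
FEATURES             Location/Qualifiers
     CDS             complement(1..1338)
                     /locus_tag="GCA_SYN0003__2_glim_g1"
                     /product="siderophore signature gene"
                     /translation="DEEEEGTIEWWQLCHGDVSSRNSKAHLWDVNNAYTNTWCHFRWK
                     YNASFIVRTIPARQNQGRKTDVAFLLGSWPWWKTAHQEQELMPRSMWEPGNFHAACTK
                     FFIVTAHRNSYKYEQFMGCYDDAPKKYYGLETFIRICVFDHNYTEKGYQKGDHCRSNH
                     PHCWMHNALSLESDNQCYDAKQSNCDQQYMHGEARCNRCIHYNRWCAAWQEEIVDDIR
                     EKDYCDMCGNWKKHCALHYVCFGWKCTKFNVGNCLGDDRMAIWLYREIFQKFIEPDGI
                     CMVRMQILPHMSWHKYDSEHEMHPVFMGLSHIVSPTSNSHAYYTHGRDSVIFRMDECW
                     QIQKYICSCRWNFEGNSSEGQAPGVWFIIVQGNKCIHADMFVKWRWGQLHGSKNTIQR
                     WFHDMAMLKFAPAQEEGKLTISFIFMMGPKIMLQHRMKIYVAPAGSWPGMFFIL"
     CDS             complement(3132..4727)
                     /locus_tag="GCA_SYN0003__2_glim_g2"
                     /product="hypothetical protein"
                     /translation="LAIYRVHFTRDGTANAHCSPMPPCRLGYHPLDDWLVEWTYDRQL
                     NVYHPLGTCKVNMYPSTFMIVGTMARFLYCSCVLDLEQTYWNLDNWSYDRGTKHKTGR
                     LRKDVDRYEDVGMNRPKEWGTPYTAKIGGEVPKDWFGPMWQTGLEQNAQYYFRKHFFE
                     DCTYMWIERRFGDDDTNATYKCKPWDSDQDWLFCHATRMPRSLYVLVVTMGTEVIWNV
                     ASAPEHLTSMQLNSLTRSEIRYQMGSEDRMRRTYMHNCYGPKTEIPRSCYQKLDGSNQ
                     IIYWQFYIGGIKAPVPQACKSDCIMPGCPSCWSMFYNPLMKMSEGYQSREHIQGMVCK
                     EVVGPKQISGEYCGMPETRATQRCFTIRGINYEIPAVSEQNSIKNEDDCGILHLKEKY
                     RRRIICDCLYYARIYSDSWQMVHQNEWKYRGVDKRFDGQSIHPSSKETNVFIICWNDQ
                     GRETCKKSTPRNHTRVNQIHMQNTTPMYNERDTPDRISSFVYEWNDQAWTLVPYHTIF
                     LKYSGLSSSPNNRNDVRKDAYPHP"
ORIGIN
//
LOCUS       GCA_SYN0003__3_glim 2833 bp    DNA     linear   UNK
DEFINITION  GCA_SYN0003__3_glim contig=ctg1 start=4008642 end=4011475.
FEATURES             Location/Qualifiers
     CDS             1..993
                     /locus_tag="GCA_SYN0003__3_glim_g1"
                     /product="NRPS-like signature gene"
                     /translation="KYCNIFGDWKNQPKFYHGMAEGGPAIDMDLQLCTYEMQEFIVTM
                     YTEITTWGIRCPQCQFHFKGFDNHQRNQGKMIRWLNLETTSATNVHTFVKWEMSHGNL
                     TGFKCRRMLQRKFEWKYYQLWGECLTGLCMPFLPFQGDKQPYWEHMTMLKDIAYTWKA
                     FGFTREELAGATDVTHNKAPMMQCSSDSNVENHMPALGHGLNQVHCWMTGSTVVSGAT
                     VFDVHMHCWQGEFMNSVLQIQMRYKITFSVEICLKEIQSSQCTMSTQIFVWFMGWHVV
                     VKYCIGGLADFDSDFQHTPRISFNNPWLNMMYRVQLMPDWCTCSSMWPCMSVEFW"
     CDS             1673..2833
                     /locus_tag="GCA_SYN0003__3_glim_g2"
                     /product="hypothetical protein"
                     /translation="HYLWRPERITIGPCTQCEHTFLYPYEVYWPACQTQHPPQNWGSY
                     GLDSVWYCFIGRCSCHKWMSHWITIGVVEFAVMIPCNPDWQCMHLKVRVQPGEILNWM
                     LGSAPCYMCPPFVYAMMNDQRAQTATEAHCLIVGMSIIADERKRDWNIFRPCQKLCFL
                     MKHYDGANNNVASKARMRIQQASWKKKVELDCKCAICMKWNDCMYWDLYGGQKRSRME
                     MVQQGWCDSLDKKIEVLPGNITNGPSGWDKGRQDFPNYNLCQRKACREHLNISILRMQ
                     GVTPQVGEAATSNCTFVNIPSKIHETTNKANGGQQNYGGQYYYFEDHFQGWMFNRPYF
                     RCDIINQAVYDKKAFDEKGGDYAQFCRRENVVDINAVCAWNCGREMVVNEVGA"
ORIGIN
//
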