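LOCUS       GCA_SYN0002__1_glim 3092 bp    DNA     linear   UNK
DEFINITION  GCA_SYN0002__1_glim contig=ctg1 start=0 end=3092.
FEATURES             Location/Qualifiers
     CDS             complement(1..990)
                     /locus_tag="GCA_SYN0002__1_glim_g1"
                     /product="terpene signature gene"
                     /translation="TYYFAQQFTVVGHDEDPEPSMTPAYGSFLIPWRGSCFECKQTSC
                     QCAVWYAQLKNPFATNAMRMLQQEKAYMNGPCLMPFYNAMHTSTEKLKLCMCYIPRMK
                     DEMYMSIASHNAKEPHRFKWKLHNHAFYKFKVSDMCDVAMHHMMFHRHPKWKPSKKGW
                     LWMPEDTDECWMKVFQREFCGWNKYMSCCYGKRAYKPAMRNAQHYNACKQQFVMYRTP
                     NNTDAGWTKRWVEQRNLQHNVRIKVKIVDTPKVKRQNKYTSFIGQPAEMCTTYQQYIP
                     TKRRRDGCSYRCYICMNSKDDDTAWDGIIRYNVVNYWSMFPICRFESDWHMAWK"
     CDS             complement(1719..3092)
                     /locus_tag="GCA_SYN0002__1_glim_g2"
                     /product="terpene signature gene"
                     /translation="KEFTMGTRCDGEGPLVLWKYNKHERIQVKCVTVQRNKSLVHWEM
                     IPKHFRAFMPNYMTQQGYKHFQFRYHGMLFQAYGMLEKHPHLPLKFHLAGLKLRNPNH
                     HVRQCTVHLNHHLRGVNTPSANMKPQTSNEREFMGWEKVIYVMPWPFPIIVQQHQEDA
                     NIRDGRKKSKPIYLENGEIYYNAVWNRSEANDVCDQFFERSDTFMYCELHLKDRVSTW
                     RNHFFRVAKMCAGGLNFAHEANAFAQKMCDKDMLFWIRGETFNRNNWCYWISTFVRNP
                     FINYQGADAMREPVCCVAKFMDEVMPWPGRCPYFWMWCFIGAYPLQFVIVWHCWNAAH
                     VELCKWVTWANGKIKVPWEERKYYKFPKKHRGTAPQCCMCFPCHYWVELYKAHTYWDK
                     YHKIWEIQNFHTTKDGHECEMWLSNAFPHDENPEVDKHDSDEGKCFRIMEVMHMPQRF
                     TVWPLLPQ"
ORIGIN
//
LOCUS       GCA_SYN0002__2_glim 3476 bp    DNA     linear   UNK
DEFINITION  GCA_SYN0002__2_glim contig=ctg1 start=2003092 end=2006568.
FEATURES             Location/Qualifiers
     CDS             complement(1..1338)
                     /locus_tag="GCA_SYN0002__2_glim_g1"
                     /product="siderophore signature gene"
                     /translation="DCEEEGTIEQWNIRQGDVSSKNSLAHLWDVNNAITNTWTHSRWK
                     YPAYDIVALIPARQNQGRKTDVAFLYGSWPWWWLAFQCQELMPRSCWVPVNFHAACTK
                     FFIVTAHRNSYKYECAMGCYDDHPKEYYGLETMIRICVFDHSYTLKGYQKGDWGRINH
                     PHCWMHNALSLESLNQCYDTKQSNCDQIYMHGEARCNACIHRNRWCAWWQEEISDDIR
                     EKHYVRMCGNWKKHCVLHYVWFGWKTTKFNVGNLLGDDRMAIWLDREIFQKFIEPDGI
                     CLVRMQILTHMVWHKYDSEHHYHPVFMGLSYIVSPTSVSHARYTHGRDSVIFIMSICW
                     QIQKYICSCRWNQPGNSSLGQAPGVWFIIVQGNKCIHLDMDIKWRWGQLSGKKNRIQH
                     WHHDMAMLKFAPAIEEKILTISDIFEMGIKIMLQHRPKIYVPPAGHWPGMFFIA"
     CDS             complement(1881..3476)
                     /locus_tag="GCA_SYN0002__2_glim_g2"
                     /product="hypothetical protein"
                     /translation="LAIYRLHFTRDGTADAECSPMPPRRLGYVPDQDWDVEYTYDRQL
                     NVYHPLGTCKVNMNPSTFMIVGTLAIFLYWSCVLDIEQTNWNLDNWSKDRGTKHKTGR
                     LRKPVDRYRDVGMNRPKHLGTPRTGKIGGEVPKCWFGHMWTTGLEQNAGNYFRKHFFE
                     DCTYMWIERIPGDDDTHAQYVCKPNDSDGDWLFCEATRMPRSLYVLVETLGTEVIWNV
                     ISWPEHLTSMRLNSLTRSEIRYQMGSNQRMRRTMFHPCYGPKTEKPRSCYQKLDGSNQ
                     IIYWQFMIGGIKATVPQACTCDNIMPGCPSCWSMFYNPLMPMPEGNQSREHIQGMVCK
                     EVVGSNGISGEYCGMPQTRATQRCHTIRGINYEIPHYSHQNSIKNADDCAILHLKEKY
                     WRRIIIDQLYYERIYWDSWQMVWTNPWKYRGVDKRRDGQSIHPSSTETNWFIINWIDQ
                     GVETCKKSTPRNHTRVNQIWMQNTTPMYNERDTPDRISSFRYVVNDQAWTLFMYHQIF
                     DIYSGLSSSTNNRNDVRFDAYGHP"
ORIGIN
//
LOCUS       GCA_SYN0002__3_glim 2530 bp    DNA     linear   UNK
DEFINITION  GCA_SYN0002__3_glim contig=ctg1 start=4006568 end=4009098.
FEATURES             Location/Qualifiers
     CDS             1..993
                     /locus_tag="GCA_SYN0002__3_glim_g1"
                     /product="NRPS-like signature gene"
                     /translation="KHSCIFGAWKNQPKDYPGMAEGGPAIDMDLQLCTYFMQEFIVTM
                     YTEITTWGIQCPQCQFHFKGWDNHQRNQGKMIRCLDLETTYATYVHEFLKAEMSHGNL
                     TGFKCREQSQRKFHWKYYQLWLECDTGICCPFGPFAGSKQPYWEHMGMLKDEAYTWKA
                     RGDTRRELAGAQDVTHNMKHMMQCSSDSNVWRHMPALGHQLNQVHCWMTISTVVSKAT
                     KFDVHMHCWMGEFMDYVNQIQMRYKPTFSVEICCKEIQSPQFTASTQHFVWFMGWHVV
                     TKYCIGGLQQFDSDFQHTPRDSFNNPRLNMMHRVQKMPDQVTCAHMWPCMSVERW"
     CDS             complement(1370..2530)
                     /locus_tag="GCA_SYN0002__3_glim_g2"
                     /product="hypothetical protein"
                     /translation="HWDQRPERICIEPCTQCEHTFLYVYEVYWPQCQTQPPPQNWGSG
                     GLDDTWYCFIGRCSCHKWMSWASTIGVVEFAVMIPCYPDYQCMHLWVRVQPGSILNWM
                     LGSAPNYTCPPFVVAMMYDQRAQTATEPHCLIVRMKICADERKIDWNIMRPCEKLTFL
                     NKWYDGAYNNVWSKAISRIQDASTKKAVELDCICAIDGKWNDCMYWDLYRFQKRNRME
                     MVQQRWKDSRDKKIEVLFKNITNMPSCWDKGRQDPPNYNLCKRYENPEHAAISICRMQ
                     GVTPQVGEAATENCTTDNIPQKIMETGNVAWGGIQNYGGFYYYLEDHMQTWMFNRPYF
                     RCDIFNQAVYDKCAFQEKGGDYVQFCRRENVWDINKSCAWNCGREMVVNECGK"
ORIGIN
//
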