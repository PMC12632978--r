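>gcommon_bd
RIFHLTVKTNTRSDVYKTLALQLDLGTDWARNLASTNREGEMDAEARSKDHNDFAIQANAQE
>bcommon_bd
AKNMIEQKDLATMENAEVEAVTLEANSVLDQEKLELFALKLSSSAQQRSAASQDNDQDKVR
>IFNAR1_bd
DAVIYKLYVAGDVITSIVRRTIDENQEEKVFTEAERTQQHQARLVAFAIDLLYLFMRVRA
>TSLPR_bd
VHTGTTSTFIQSRAIRDVGEYMWAKLFAHRNMLLVDAFELEDISIRVLGAAAAEKATRLLRAA
>IL12Rb1_bd
LEAEFIAALAKDAINNRAKDIKELKEELLQANKIAEAGWDELQAAAGAQESKRFDFEKLHRRLQFIRLLALAVEVIQEMHAQLKVLQVTARLTKKGYEL
>IFNAR2_bd
AAEAQINDDFKEVKTNAGSKSEVEQAIWAAASQHEHEGGTQLQEAQVFQWASLQTAVGDAMQRIDLQGLAEGGKAHRS
>IL10Rb_bd
ILGNAGRALNNAASGDLAMHVLEDVETATQNIMQTNKEAWSLQIAYIANQALQQTDALELILIWIADKDLLLTVRETYKGVK
>IL4Ra_bd
ANKRTDQRNSALQSQRQGAEDANKRTTQLQTAKIRELQKASDETAGEFAVVNNLMVKWALDIALTALFKGVLDVNAQERASESEELGLLLSILRLFWLRDEELQFVVAQAKEVGTELDDEETQLSNKLT
>IL2Rb_bd
IIENAKEADKEGQVDREMREAQMDQLVILEHQEIYLNIVVALELINRIELQFLEVTRQLLKITEAIDLVLDIKGHQNQETIFKMEFLVSNEDAQEHDNHY
>IL7Ra_bd
VGGMDLAQEHAYVFDLLIEVIEEDDFLNKDRIAITLATEKVAVLEALEAENTGMIKDAVVRIKA
>IL10Ra_bd
LAVRNWIATIQLLAIKLKIRLLIANADIEELALIEIKVRLKLTVKADYIDALREIEQLEDFVRSI
>IL17Ra_bd
LAILTAHVQKIVREILNEWKMKNGQQFQEQEHVDSDIATKLQKDSLETFSTQLEATEQLQ
>IL21Ra_bd
AGSKFNDSYISKIQSATDLLLLSVELKADLERVAKQDAKTQEATARQHLFQNVGLAEHITDLQADH
>IL23Ra_bd
SIEELTLLAFDLELKTSRHNSAREKDLEFDRHIWMEQALKTIKVLARKQAAEVTLSLVFQIQDSGTYMEL
>gp130_bd
AVKHEAKLFHLALIQADDEDETELLQRRLFQELTATRIAVLVIDEDSWVKIFQYTVALEVLL
>IFNLR_bd
LRASAMEGFLAASIAASFGRGKVLAAMITQSGLAAEEMVTSHENHALFTKDIRAAMMEDKL
>OX40_bd
LKAMARDDVYIKGQARIQLQTVGLDIAIVQDSETMNNRQMNLKKDVLLTEMFLDWEAR
>41BB_bd
TDAMKDSLFIKTRSIRAAQFHKELIIQRQHLEAKLFGTKVDEIILFAAKMSGSLTLEDQ
>TNFR1_bd
HLATVTATVEKLTISSLAVRDTFQDLKAGRLLAVESNMLLESIATAIAMKADFVTTYIDN
>TNFR2_bd
NRASKIRLTKVAVNAMETQATSRAHQKELDEGQKQSWIADQKNKYHLVTASNKGLTRIFQ
>CTLA4_bd
TEARASSIKLMELVKIRVASENAAVLTRYLRSEAALVQNSTAEIIQSNVQELISIQM
>PDL1_bd
FQKTALIMLNGVLAIQINAFHDANIELNVEKETKEDDTSNDYEDLAGKAELRLQVAK
>cKit_bd
EIAVAWIAASEERYKDALIYAVVLYYEFHSDVAEANANEATKEKRLKQAKRAISYTVLKFARDLE
>IGF1R_bd
LKLQTVNLKKAVKEIQVALAEAKHQAQETAHYNDSITAIVRVDSLNLENLLEYGEKLTSKDKLL
>HER2_bd
AGNVFTIQWEVAYFEKASAWENKVLDTDFSKKTKLTSTADALKAKLVWATHAIRAAAA
>FGFR_bd
WETLNVQFQENKEEGIDINAWRAIIRLEEKLHDERDITILKLTAAKIKTLAKGLEGEIQALAA
>EGFR_bd
VVEDNESSHWVQALKGDNLKALVTSTSLNVSREAELNRTRIEMTATDVEIQLISKW
>BMPR2_bd
TTELYIKLSLTTKFYLKLTEIERTKLGMENVQETKEFKGVRLKREKNEIATIALAKGLWENF
>ActRII_bd
AFNKLAVQYLAVELEKSAAAHRFEAHQLVDESRRKAQKAVDKGIVQREKLLERTEANSQEL
>INSR_bd
KVDEFILVYNEKKESALIVALKVKELKKAGEDTNQGAVERNNTIKNVTDNFAVEKMKEKIKITKIK
>TrkA_bd
ATIENLRQEDQNEHELKETLVLLAQEIERQSAEHHEVAELNSSEQLENVAEAYQDIDRDRRATN
>TGFbR2_bd
NEVLDEKIDEAWLLEQVDEGNKLQAIYVGDMEKKELGEVVSRELAFKEWIVAAEEESKKM
>ALK1_bd
QFTQAAIEQVANAEAQAEKQTEELLAKKYNERKKQSFMEGGILIALYIRREMMQENLFI
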