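((Acidobacteria,Aquificae,Atribacterota,Caldiserica_Cryosericota,Calditrichaeota,Chrysiogenetes,Coprothermobacterota,Deferribacteres,Desulfobacterota,Dictyoglomi,Elusimicrobia,(Bacteroidetes_Chlorobi,Fibrobacteres,Gemmatimonadetes)FCB_group,Fusobacteria,Myxococcota,Nitrospinae_Tectomicrobia,Nitrospirae,(Alphaproteobacteria,Gammaproteobacteria,Deltaproteobacteria)Pseudomonadota,(Chlamydiae,Lentisphaerae,Planctomycetota,Verrucomicrobia)PVC_group,Spirochaetes,Synergistetes,(Actinomycetota,Bacillota,Chloroflexi,Cyanobacteria,Deinococcus_Thermus,Tenericutes)Terrabacteria_group,Thermodesulfobacteria,Thermotogae,Bacteria_candidate_phyla)Bacteria,((Asgard_group,Thermoplasmatota,DPANN_group,Euryarchaeota,TACK_group)Archaea,(((Chloroplastida,Glaucophyta,Rhodophyta,Picozoa,Cryptista,Haptophyta,Centroheliozoa,Provora,Hemimastigophora,Telonemia,Stramenopiles,Alveolata,Rhizaria)Diaphoretickes,(Amoebozoa,(((Basal_metazoans,(Protostomia,Deuterostomia)Bilateria)Metazoa,Choanoflagellata,Filasterea,Tunicaraptor,Pluriformea,Ichthyosporea,Rotosphaerida,Fungi)Opisthokonta,Breviatea,Apusozoa)Obazoa,CRuMs,Ancyromonadida,Malawimonadida)Amorphea,(Discoba,Metamonada)Excavata)LECA)FECA)Archaea_Eukaryota)LUCA;
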