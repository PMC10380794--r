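taxon	clade	domain
Metazoa_sp1	Metazoa	Eukaryota
Metazoa_sp2	Metazoa	Eukaryota
Fungus_sp1	Ascomycota	Eukaryota
Plant_sp1	Chloroplastida	Eukaryota
Stramenopile_sp1	Stramenopiles	Eukaryota
Discoba_sp1	Discoba	Eukaryota
Amoebozoa_sp1	Amoebozoa	Eukaryota
Haptophyte_sp1	Haptophyta	Eukaryota
Cyanobacteria_sp1	Cyanobacteria	Bacteria
Cyanobacteria_sp2	Cyanobacteria	Bacteria
Rotifer_sp1	Rotifera	Eukaryota
Rotifer_sp2	Rotifera	Eukaryota
Bacteroidetes_sp1	Bacteroidetes	Bacteria
Bacteroidetes_sp2	Bacteroidetes	Bacteria
Ascomycota_c2_sp1	Ascomycota	Eukaryota
Planctomycetota_sp1	Planctomycetota	Bacteria
Planctomycetota_sp2	Planctomycetota	Bacteria
GreenAlga_sp1	Chlorophyta	Eukaryota
GreenAlga_sp2	Chlorophyta	Eukaryota
Chytrid_sp1	Chytridiomycota	Eukaryota
Chytrid_sp2	Chytridiomycota	Eukaryota
Streptomycetes_sp1	Streptomycetes	Bacteria
Streptomycetes_sp2	Streptomycetes	Bacteria
Ascomycota_c4_sp1	Ascomycota	Eukaryota
Ascomycota_c4_sp2	Ascomycota	Eukaryota
Gammaproteobacteria_sp1	Gammaproteobacteria	Bacteria
Gammaproteobacteria_sp2	Gammaproteobacteria	Bacteria
Dinoflagellate_sp1	Dinoflagellata	Eukaryota
Dinoflagellate_sp2	Dinoflagellata	Eukaryota
OtherBacterium_sp1	OtherBacteria	Bacteria
OtherBacterium_sp2	OtherBacteria	Bacteria
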