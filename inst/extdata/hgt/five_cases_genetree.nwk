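(((GreenAlga_sp2:0.3543072263,(Chytrid_sp2:0.2910633054,(Planctomycetota_sp2:0.02898006726,(Chytrid_sp1:0.3126913657,(Planctomycetota_sp1:0.01251890686,GreenAlga_sp1:0.3090647173):0.02041578342):0.01489270561):0.01048805042):0.03807235478):0.4257085458,((Discoba_sp1:0.3264643579,(Plant_sp1:0.3422495496,(Stramenopile_sp1:0.3118298114,(Fungus_sp1:0.2735055821,(Haptophyte_sp1:0.2694878574,(Metazoa_sp1:0.3576899825,(Metazoa_sp2:0.2984631649,Amoebozoa_sp1:0.3863852129):0.0247100281):0.02562887602):0.04065520613):0.02915929006):0.03401083446):0.004029316999):0.8320505092,((Streptomycetes_sp1:0.0007485556328,Ascomycota_c4_sp2:0.3618965553):0.01793934677,(Streptomycetes_sp2:0.02515147012,Ascomycota_c4_sp1:0.3434996649):0.007944173024):0.2975783221):0.03630035158):0.04267750388,(OtherBacterium_sp1:0.4103287288,(Rotifer_sp2:0.3058785636,(Cyanobacteria_sp1:0.06011473657,(Cyanobacteria_sp2:0.0399890197,Rotifer_sp1:0.3226560912):0.007764259847):0.05019739199):0.2932658549):0.03462855934,((Dinoflagellate_sp2:0.3544132814,(Dinoflagellate_sp1:0.3227296967,(Gammaproteobacteria_sp1:0.0517226165,Gammaproteobacteria_sp2:0.0490189533):0.02928817304):0.02942069857):0.262512966,(OtherBacterium_sp2:0.3762801206,(Ascomycota_c2_sp1:0.3166524653,(Bacteroidetes_sp1:0.03925089556,Bacteroidetes_sp2:0.02528762558):0.0441208622):0.3907863513):0.0210251634):0.01792230906);
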