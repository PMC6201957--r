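lineages:
- p__Ascomycota;c__Class1;o__Order1;f__Family1;g__Genus1;s__Genus1_sp1
- p__Ascomycota;c__Class1;o__Order1;f__Family1;g__Genus1;s__Genus1_sp2
- p__Ascomycota;c__Class1;o__Order1;f__Family1;g__Genus1;s__Genus1_sp3
- p__Basidiomycota;c__Class1;o__Order2;f__Family2;g__Genus2;s__Genus2_sp1
- p__Basidiomycota;c__Class1;o__Order2;f__Family2;g__Genus2;s__Genus2_sp2
- p__Basidiomycota;c__Class1;o__Order2;f__Family2;g__Genus2;s__Genus2_sp3
region_params:
  ITS1:
    mean_length: 177.0
    sd_length: 45.0
    gc_target: 0.5
    interspecies_rate: 0.032
    intraspecies_rate: 0.013
  5.8S:
    mean_length: 158.0
    sd_length: 0.0
    gc_target: 0.5
    interspecies_rate: 0.0
    intraspecies_rate: 0.0
  ITS2:
    mean_length: 182.0
    sd_length: 30.0
    gc_target: 0.55
    interspecies_rate: 0.016
    intraspecies_rate: 0.0065
anchors:
  ssu_tail: TCCGTAGGTGAACCTGCGG
  r58s_head: AACTTTCAACAACGGATCTC
  r58s_tail: GCATCGATGAAGAACGCAGC
  lsu_head: GCATATCAATAAGCGGAGGA
  max_mismatch: 2
samples:
- sample: S1
  species: Genus1_sp1
  copies: 5
- sample: S1
  species: Genus1_sp2
  copies: 5
- sample: S1
  species: Genus1_sp3
  copies: 5
- sample: S1
  species: Genus2_sp1
  copies: 5
- sample: S1
  species: Genus2_sp2
  copies: 5
- sample: S1
  species: Genus2_sp3
  copies: 5
seed: 7
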