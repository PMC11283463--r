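region:
  name: synthetic_ABC
  chrom: chrX
  start: 1228310
  end: 1228969
  sequence: TATATTCTTAAAAAAGATTGTGTGTAGCTAGCTACGTGCATCTCTTGCATTAAATAAATATGCTTTTTAGTTTCTGCTCATTCCATGATGCATTCTTAAGTTATTGCTATAGCTACGTACTTTTTACCTAACTTTATATGGAACAGCAAATCAAGCCTAGCTTAAAAGGCTTTCTTCTTGAGCTATAAACCAGCTACGTGTCCCTCCTATTGAATGCTTATTGCAGAATATTCTTATGCTAGGGAGGAAATCTTCCTAGGTCAGGCTACCTGTAGCTACGTAATTGGCATAGTGTAGGTTCTCTTCTGTCTCTTTGGGTGTTTCTCTTTCAATTATTACTGTTATAGCTGAAGAAGCTACGTGATGTTGCTTTTTAATAGTATACTTTCTTTCTTTAAGATATTCTGCCTAGACACAGGGCTGCATACAACATAACAGCTACGTTGTTGAATGGAGCTATGCTCTCAATTATTACCTGTTATCAATACTACTTTATTACTAGTTTTGAGTTTATCAAAGCTACGTAGCCAGCCCAATGCCTGGCCCTTGCACTCTCTAATCAGCCTCTGCTTGTTTGAGTCTAGTCTCACTAGGCCTTAAGCTACGTTGACATCTTATGACTATTCTCTAGGAATAACTTTTTTTATGTTCTGGCTGGTT
panel:
  chamber_volume: 0.00045
  probes:
  - probe: FAM_drop
    channel: FAM
    window:
    - 1228334
    - 1228353
    reference: no
  - probe: TAMRA_drop
    channel: TAMRA
    window:
    - 1228415
    - 1228434
    reference: no
  - probe: Cy5_drop
    channel: Cy5
    window:
    - 1228496
    - 1228515
    reference: no
  - probe: SUN_ref
    channel: SUN
    window:
    - 1228378
    - 1228397
    reference: yes
simulation:
  chamber_count: 20000
  classes:
  - label: WT
    intact_channels:
    - FAM
    - TAMRA
    - Cy5
    - SUN
    concentration: 99.0
  - label: TAMRA_dropout
    intact_channels:
    - FAM
    - Cy5
    - SUN
    concentration: 11.0
mutation_model:
  substitution_rate: 0.02
  indel_rate: 0.05
  cpg_kernel: 0.7
  cpg_window: 8
  at_cpg_bias: 1.3
  deletion_fraction: 0.8
  length_geometric_p: 0.6
reads:
  read_count: 2000
  error_rate: 0.001
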