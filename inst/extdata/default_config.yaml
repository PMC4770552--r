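# Default synthetic end-to-end run.  Every analysis parameter is explicit;
# primer sequences are synthetic stand-ins (real primer sequences are
# supplied the same way by the user).
seed: 1
outdir: nirkit_out

synthetic:
  n_clade1: 10
  n_clade2: 10
  n_bacillus_loop: 0
  substitution_rate: 0.0
  fraction_with_heme_ext: 0.15
  fraction_with_cupredoxin_ext: 0.15
  multi_copy_fraction: 0.05

reference: bundled

nj:
  method: count_differences   # amino-acid "number of differences"
  deletion: complete
  replicates: 100

primers:
  three_prime_window: 3
  max_mismatch: 2
  definitions:
    - name: synthF1
      sequence: ATYGGNGGNCAYGARCA
      orientation: forward
    - name: synthR1
      sequence: GCNGWRCACCANGTRTG
      orientation: reverse
  plant_mismatches:
    I:  [0.02]
    II: [0.15]

inventory:
  multi_copy_fraction: 0.05
  associations:
    - genes: [narG, nrfA]
      or: 0.2
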