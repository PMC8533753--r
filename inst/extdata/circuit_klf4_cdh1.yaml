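variant: klf4_cdh1
signal:
  node: Iext
  value: 0.0
nodes:
- name: Iext
  kind: protein
  g: 0.0
  k: 1.0
  clamped: yes
- name: miR200
  kind: microRNA
  g: 2100.0
  k: 0.05
  clamped: no
- name: ZEBm
  kind: mRNA
  g: 11.0
  k: 0.5
  clamped: no
- name: ZEB
  kind: protein
  g: 100.0
  k: 0.1
  clamped: no
- name: SNAIL
  kind: protein
  g: 12000.0
  k: 0.1
  clamped: no
- name: SLUG
  kind: protein
  g: 8000.0
  k: 0.1
  clamped: no
- name: KLF4
  kind: protein
  g: 5000.0
  k: 0.1
  clamped: no
- name: CDH1
  kind: mRNA
  g: 2000.0
  k: 0.1
  clamped: no
edges:
- source: Iext
  target: SNAIL
  sign: activation
  mode: transcriptional
  threshold: 104000.0
  hill: 2.0
  lambda: 12.0
- source: SNAIL
  target: SNAIL
  sign: inhibition
  mode: transcriptional
  threshold: 200000.0
  hill: 1.0
  lambda: 0.1
- source: SNAIL
  target: miR200
  sign: inhibition
  mode: transcriptional
  threshold: 180000.0
  hill: 2.0
  lambda: 0.1
- source: SNAIL
  target: ZEBm
  sign: activation
  mode: transcriptional
  threshold: 180000.0
  hill: 2.0
  lambda: 6.0
- source: SLUG
  target: miR200
  sign: inhibition
  mode: transcriptional
  threshold: 60000.0
  hill: 2.0
  lambda: 0.3
- source: SLUG
  target: ZEBm
  sign: activation
  mode: transcriptional
  threshold: 60000.0
  hill: 2.0
  lambda: 2.5
- source: SLUG
  target: SNAIL
  sign: inhibition
  mode: transcriptional
  threshold: 200000.0
  hill: 2.0
  lambda: 0.7
- source: SNAIL
  target: SLUG
  sign: inhibition
  mode: transcriptional
  threshold: 200000.0
  hill: 2.0
  lambda: 0.7
- source: miR200
  target: SLUG
  sign: inhibition
  mode: transcriptional
  threshold: 10000.0
  hill: 2.0
  lambda: 0.2
- source: ZEB
  target: miR200
  sign: inhibition
  mode: transcriptional
  threshold: 220000.0
  hill: 3.0
  lambda: 0.1
- source: ZEB
  target: ZEBm
  sign: activation
  mode: transcriptional
  threshold: 25000.0
  hill: 2.0
  lambda: 7.5
- source: KLF4
  target: SNAIL
  sign: inhibition
  mode: transcriptional
  threshold: 30000.0
  hill: 2.0
  lambda: 0.3
- source: SNAIL
  target: KLF4
  sign: inhibition
  mode: transcriptional
  threshold: 150000.0
  hill: 2.0
  lambda: 0.25
- source: KLF4
  target: SLUG
  sign: inhibition
  mode: transcriptional
  threshold: 30000.0
  hill: 2.0
  lambda: 0.5
- source: SLUG
  target: KLF4
  sign: inhibition
  mode: transcriptional
  threshold: 100000.0
  hill: 2.0
  lambda: 0.3
- source: ZEB
  target: CDH1
  sign: inhibition
  mode: transcriptional
  threshold: 300000.0
  hill: 2.0
  lambda: 0.05
- source: SLUG
  target: CDH1
  sign: inhibition
  mode: transcriptional
  threshold: 60000.0
  hill: 2.0
  lambda: 0.3
mirna_module:
  mir: miR200
  mrna: ZEBm
  protein: ZEB
  u0: 10000.0
  l:
  - 1.0
  - 0.6
  - 0.3
  - 0.1
  - 0.05
  - 0.05
  - 0.05
  gamma_m:
  - 0.0
  - 0.04
  - 0.2
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  gamma_u:
  - 0.0
  - 0.005
  - 0.05
  - 0.5
  - 0.5
  - 0.5
  - 0.5
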