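# Default diagnostic label hierarchy: raw label -> detailed class -> coarse
# class. The order of coarse_classes fixes the probability-vector index order
# everywhere in the package. Exactly 6 coarse classes are malignant; the two
# non-malignant classes must be "reactive changes" and "healthy".
coarse_classes:
  - acute leukemia
  - MDS
  - MDS/MPN
  - MPN
  - lymphoma
  - plasma cell neoplasm
  - reactive changes
  - healthy

malignant:
  acute leukemia: true
  MDS: true
  MDS/MPN: true
  MPN: true
  lymphoma: true
  plasma cell neoplasm: true
  reactive changes: false
  healthy: false

detailed_to_coarse:
  AML: acute leukemia
  ALL: acute leukemia
  MDS: MDS
  MDS/MPN: MDS/MPN
  ET: MPN
  PV: MPN
  CML: MPN
  other MPN: MPN
  CLL: lymphoma
  lymphoma (excluding CLL): lymphoma
  multiple myeloma: plasma cell neoplasm
  MGUS: plasma cell neoplasm
  reactive changes: reactive changes
  healthy: healthy

# Raw laboratory labels are site-specific; these aliases cover common
# spellings and subtypes. Detailed and coarse class names may also be used
# directly as labels.
raw_to_detailed:
  acute myeloid leukemia: AML
  acute lymphoblastic leukemia: ALL
  APL: AML
  acute promyelocytic leukemia: AML
  myelodysplastic syndrome: MDS
  CMML: MDS/MPN
  essential thrombocythemia: ET
  polycythemia vera: PV
  chronic myeloid leukemia: CML
  myelofibrosis: other MPN
  chronic lymphocytic leukemia: CLL
  B-cell lymphoma: lymphoma (excluding CLL)
  T-cell lymphoma: lymphoma (excluding CLL)
  plasma cell myeloma: multiple myeloma
  monoclonal gammopathy of undetermined significance: MGUS
  reactive: reactive changes
  stem cell donor: healthy
  normal: healthy
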