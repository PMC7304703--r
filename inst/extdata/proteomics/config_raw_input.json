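{
  "_comment": "Specification with a Thermo RAW mass-spectrum input and three use_operation constraints. No annotated tool consumes RAW or performs PSM validation, so this specification has no solution within the length bounds.",
  "ontology_path": "edam_fragment_synthetic.owl",
  "tool_annotations_path": "tools.json",
  "operation_root": "http://flowsynth.example.org/proteomics#Operation",
  "data_roots": [
    "http://flowsynth.example.org/proteomics#Data",
    "http://flowsynth.example.org/proteomics#Format"
  ],
  "inputs": [
    {
      "http://flowsynth.example.org/proteomics#Data": ["http://flowsynth.example.org/proteomics#Mass_spectrum"],
      "http://flowsynth.example.org/proteomics#Format": ["http://flowsynth.example.org/proteomics#Thermo_RAW_format"]
    }
  ],
  "outputs": [
    {
      "http://flowsynth.example.org/proteomics#Data": ["http://flowsynth.example.org/proteomics#Amino_acid_index_hydropathy"]
    }
  ],
  "constraints": [
    {
      "template": "use_operation",
      "args": ["http://flowsynth.example.org/proteomics#Peptide_identification_op"]
    },
    {
      "template": "use_operation",
      "args": ["http://flowsynth.example.org/proteomics#Validation_of_peptide_spectrum_matches"]
    },
    {
      "template": "use_operation",
      "args": ["http://flowsynth.example.org/proteomics#Retention_time_prediction"]
    }
  ],
  "max_length": 3,
  "output_dir": "out"
}
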