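{
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
      "http://flowsynth.example.org/proteomics#Format": ["http://flowsynth.example.org/proteomics#mzML"]
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
      "args": ["http://flowsynth.example.org/proteomics#Retention_time_prediction"]
    }
  ],
  "min_length": 1,
  "max_length": 3,
  "max_solutions": 50,
  "output_dir": "out",
  "exports": {"text": true, "dot": true, "shell": true, "cwl": true}
}
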