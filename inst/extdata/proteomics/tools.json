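{
  "_comment": "Six proteomics tools with operation / input / output annotations. Shell commands are synthetic stubs for testing script export (SSRCalc deliberately has none).",
  "functions": [
    {
      "id": "comet",
      "label": "Comet",
      "operation": ["http://flowsynth.example.org/proteomics#Peptide_database_search"],
      "inputs": [
        {
          "http://flowsynth.example.org/proteomics#Data": ["http://flowsynth.example.org/proteomics#Mass_spectrum"],
          "http://flowsynth.example.org/proteomics#Format": [
            "http://flowsynth.example.org/proteomics#mzML",
            "http://flowsynth.example.org/proteomics#mzXML"
          ]
        }
      ],
      "outputs": [
        {
          "http://flowsynth.example.org/proteomics#Data": ["http://flowsynth.example.org/proteomics#Peptide_identification_data"],
          "http://flowsynth.example.org/proteomics#Format": ["http://flowsynth.example.org/proteomics#pepXML"]
        }
      ],
      "implementation": {"shell_command": "cat {in1} > {out1}"}
    },
    {
      "id": "msconvert",
      "label": "msconvert",
      "operation": [
        "http://flowsynth.example.org/proteomics#Formatting",
        "http://flowsynth.example.org/proteomics#Filtering"
      ],
      "inputs": [
        {
          "http://flowsynth.example.org/proteomics#Data": ["http://flowsynth.example.org/proteomics#Mass_spectrum"],
          "http://flowsynth.example.org/proteomics#Format": [
            "http://flowsynth.example.org/proteomics#MGF",
            "http://flowsynth.example.org/proteomics#mzXML",
            "http://flowsynth.example.org/proteomics#mzML"
          ]
        }
      ],
      "outputs": [
        {
          "http://flowsynth.example.org/proteomics#Data": ["http://flowsynth.example.org/proteomics#Mass_spectrum"],
          "http://flowsynth.example.org/proteomics#Format": [
            "http://flowsynth.example.org/proteomics#MGF",
            "http://flowsynth.example.org/proteomics#mzXML",
            "http://flowsynth.example.org/proteomics#mzML"
          ]
        }
      ],
      "implementation": {"shell_command": "cat {in1} > {out1}"}
    },
    {
      "id": "peptide_prophet",
      "label": "Peptide Prophet",
      "operation": [
        "http://flowsynth.example.org/proteomics#Peptide_identification_op",
        "http://flowsynth.example.org/proteomics#Statistical_modelling"
      ],
      "inputs": [
        {
          "http://flowsynth.example.org/proteomics#Data": ["http://flowsynth.example.org/proteomics#Peptide_identification_data"],
          "http://flowsynth.example.org/proteomics#Format": [
            "http://flowsynth.example.org/proteomics#pepXML",
            "http://flowsynth.example.org/proteomics#mzIdentML"
          ]
        }
      ],
      "outputs": [
        {
          "http://flowsynth.example.org/proteomics#Data": ["http://flowsynth.example.org/proteomics#Peptide_identification_data"],
          "http://flowsynth.example.org/proteomics#Format": ["http://flowsynth.example.org/proteomics#pepXML"]
        }
      ],
      "implementation": {"shell_command": "cat {in1} > {out1}"}
    },
    {
      "id": "rt4",
      "label": "rt4",
      "operation": ["http://flowsynth.example.org/proteomics#Retention_time_prediction"],
      "inputs": [
        {
          "http://flowsynth.example.org/proteomics#Data": ["http://flowsynth.example.org/proteomics#Peptide_property"],
          "http://flowsynth.example.org/proteomics#Format": [
            "http://flowsynth.example.org/proteomics#TSV",
            "http://flowsynth.example.org/proteomics#pepXML"
          ]
        }
      ],
      "outputs": [
        {
          "http://flowsynth.example.org/proteomics#Data": ["http://flowsynth.example.org/proteomics#Amino_acid_index_hydropathy"],
          "http://flowsynth.example.org/proteomics#Format": [
            "http://flowsynth.example.org/proteomics#TSV",
            "http://flowsynth.example.org/proteomics#XML"
          ]
        }
      ],
      "implementation": {"shell_command": "cat {in1} > {out1}"}
    },
    {
      "id": "xml2tsv",
      "label": "xml2tsv",
      "operation": ["http://flowsynth.example.org/proteomics#Conversion"],
      "inputs": [
        {
          "http://flowsynth.example.org/proteomics#Data": ["http://flowsynth.example.org/proteomics#Peptide_identification_data"],
          "http://flowsynth.example.org/proteomics#Format": ["http://flowsynth.example.org/proteomics#mzIdentML"]
        }
      ],
      "outputs": [
        {
          "http://flowsynth.example.org/proteomics#Data": ["http://flowsynth.example.org/proteomics#Peptide_identification_data"],
          "http://flowsynth.example.org/proteomics#Format": ["http://flowsynth.example.org/proteomics#TSV"]
        }
      ],
      "implementation": {"shell_command": "cat {in1} > {out1}"}
    },
    {
      "id": "ssrcalc",
      "label": "SSRCalc",
      "operation": ["http://flowsynth.example.org/proteomics#Retention_time_prediction"],
      "inputs": [
        {
          "http://flowsynth.example.org/proteomics#Data": ["http://flowsynth.example.org/proteomics#Peptide_property"],
          "http://flowsynth.example.org/proteomics#Format": [
            "http://flowsynth.example.org/proteomics#Textual_format",
            "http://flowsynth.example.org/proteomics#TSV"
          ]
        }
      ],
      "outputs": [
        {
          "http://flowsynth.example.org/proteomics#Data": ["http://flowsynth.example.org/proteomics#Amino_acid_index_hydropathy"],
          "http://flowsynth.example.org/proteomics#Format": ["http://flowsynth.example.org/proteomics#Textual_format"]
        }
      ]
    }
  ]
}
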