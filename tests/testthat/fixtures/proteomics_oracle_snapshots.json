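{
  "constrained_query": ["comet@01;comet@01;rt4@01", "comet@01;comet@01;rt4@02", "comet@01;msconvert@01;rt4@01", "comet@01;msconvert@01;rt4@02", "comet@01;msconvert@02;rt4@01", "comet@01;msconvert@02;rt4@02", "comet@01;msconvert@03;rt4@01", "comet@01;msconvert@03;rt4@02", "comet@01;peptide_prophet@01;rt4@01", "comet@01;peptide_prophet@01;rt4@02", "comet@01;rt4@01", "comet@01;rt4@01;comet@01", "comet@01;rt4@01;msconvert@01", "comet@01;rt4@01;msconvert@02", "comet@01;rt4@01;msconvert@03", "comet@01;rt4@01;peptide_prophet@01", "comet@01;rt4@01;rt4@01", "comet@01;rt4@01;rt4@02", "comet@01;rt4@01;ssrcalc@01", "comet@01;rt4@02", "comet@01;rt4@02;comet@01", "comet@01;rt4@02;msconvert@01", "comet@01;rt4@02;msconvert@02", "comet@01;rt4@02;msconvert@03", "comet@01;rt4@02;peptide_prophet@01", "comet@01;rt4@02;rt4@01", "comet@01;rt4@02;rt4@02", "msconvert@01;comet@01;rt4@01", "msconvert@01;comet@01;rt4@02", "msconvert@02;comet@01;rt4@01", "msconvert@02;comet@01;rt4@02", "msconvert@03;comet@01;rt4@01", "msconvert@03;comet@01;rt4@02"],
  "pepid_tsv": ["comet@01;comet@01;rt4@01", "comet@01;msconvert@01;rt4@01", "comet@01;msconvert@02;rt4@01", "comet@01;msconvert@03;rt4@01", "comet@01;peptide_prophet@01;rt4@01", "comet@01;rt4@01", "comet@01;rt4@01;comet@01", "comet@01;rt4@01;msconvert@01", "comet@01;rt4@01;msconvert@02", "comet@01;rt4@01;msconvert@03", "comet@01;rt4@01;peptide_prophet@01", "comet@01;rt4@01;rt4@01", "comet@01;rt4@01;rt4@02", "comet@01;rt4@01;ssrcalc@01", "comet@01;rt4@02;rt4@01", "msconvert@01;comet@01;rt4@01", "msconvert@02;comet@01;rt4@01", "msconvert@03;comet@01;rt4@01"]
}
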