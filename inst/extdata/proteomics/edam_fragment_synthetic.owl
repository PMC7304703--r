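<?xml version="1.0"?>
<!-- Synthetic EDAM-style ontology fragment for the proteomics example
     domain.  The class hierarchy is a reconstruction for testing and
     demonstration; IRIs are local, not real EDAM identifiers. -->
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"
         xmlns:owl="http://www.w3.org/2002/07/owl#">
  <!-- operation dimension -->
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#Operation">
    <rdfs:label>Operation</rdfs:label>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#Peptide_identification_op">
    <rdfs:label>Peptide identification</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#Operation"/>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#Peptide_database_search">
    <rdfs:label>Peptide database search</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#Peptide_identification_op"/>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#Validation_of_peptide_spectrum_matches">
    <rdfs:label>Validation of peptide spectrum matches</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#Peptide_identification_op"/>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#Retention_time_prediction">
    <rdfs:label>Retention time prediction</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#Operation"/>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#Formatting">
    <rdfs:label>Formatting</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#Operation"/>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#Conversion">
    <rdfs:label>Conversion</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#Formatting"/>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#Filtering">
    <rdfs:label>Filtering</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#Operation"/>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#Statistical_modelling">
    <rdfs:label>Statistical modelling</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#Operation"/>
  </owl:Class>
  <!-- data type dimension -->
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#Data">
    <rdfs:label>Data</rdfs:label>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#Mass_spectrum">
    <rdfs:label>Mass spectrum</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#Data"/>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#Peptide_property">
    <rdfs:label>Peptide property</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#Data"/>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#Peptide_identification_data">
    <rdfs:label>Peptide identification</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#Peptide_property"/>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#Amino_acid_index_hydropathy">
    <rdfs:label>Amino acid index (hydropathy)</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#Peptide_identification_data"/>
  </owl:Class>
  <!-- data format dimension -->
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#Format">
    <rdfs:label>Format</rdfs:label>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#XML">
    <rdfs:label>XML</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#Format"/>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#mzML">
    <rdfs:label>mzML</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#XML"/>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#mzXML">
    <rdfs:label>mzXML</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#XML"/>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#pepXML">
    <rdfs:label>pepXML</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#XML"/>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#mzIdentML">
    <rdfs:label>mzIdentML</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#XML"/>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#Textual_format">
    <rdfs:label>Textual format</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#Format"/>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#TSV">
    <rdfs:label>TSV</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#Textual_format"/>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#MGF">
    <rdfs:label>MGF</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#Textual_format"/>
  </owl:Class>
  <owl:Class rdf:about="http://flowsynth.example.org/proteomics#Thermo_RAW_format">
    <rdfs:label>Thermo RAW format</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://flowsynth.example.org/proteomics#Format"/>
  </owl:Class>
</rdf:RDF>
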