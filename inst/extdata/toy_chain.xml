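<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_chain" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_A_c" name="A" compartment="c" constant="false"
               boundaryCondition="false" hasOnlySubstanceUnits="false"/>
      <species id="M_B_c" name="B" compartment="c" constant="false"
               boundaryCondition="false" hasOnlySubstanceUnits="false"/>
      <species id="M_C_c" name="C" compartment="c" constant="false"
               boundaryCondition="false" hasOnlySubstanceUnits="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="minus_one" value="-1" constant="true"/>
      <parameter id="zero" value="0" constant="true"/>
      <parameter id="big" value="1000" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_g_R1" fbc:label="g_R1"/>
      <fbc:geneProduct fbc:id="G_g_R2" fbc:label="g_R2"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="R_EX_A" reversible="true" fast="false"
                fbc:lowerFluxBound="minus_one" fbc:upperFluxBound="minus_one">
        <listOfReactants>
          <speciesReference species="M_A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_R1" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="M_A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_B_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_g_R1"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_R2" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="M_B_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_C_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_g_R2"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_EX_C" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="big">
        <listOfReactants>
          <speciesReference species="M_C_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
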