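<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="toy5" name="five reaction demonstration model">
    <listOfCompartments>
      <compartment id="c"/>
      <compartment id="e"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="glc_b" name="glucose (boundary)" compartment="e" boundaryCondition="true"/>
      <species id="glc_c" name="glucose" compartment="c"/>
      <species id="g6p_c" name="glucose 6-phosphate" compartment="c"/>
      <species id="f6p_c" name="fructose 6-phosphate" compartment="c"/>
      <species id="prec_c" name="biomass precursor" compartment="c"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="GLCt" name="glucose transport" reversible="true">
        <listOfReactants>
          <speciesReference species="glc_b" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="glc_c" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="-1000"/>
            <parameter id="UPPER_BOUND" value="10"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="0"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="HEX1" name="hexokinase" reversible="false">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>GENE_ASSOCIATION: YFR053C or YGL253W</p>
          </body>
        </notes>
        <listOfReactants>
          <speciesReference species="glc_c" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="g6p_c" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="0"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="PGI" name="phosphoglucose isomerase" reversible="true">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>GENE_ASSOCIATION: YBR196C</p>
          </body>
        </notes>
        <listOfReactants>
          <speciesReference species="g6p_c" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="f6p_c" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="-1000"/>
            <parameter id="UPPER_BOUND" value="1000"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="0"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="PREC" name="precursor synthesis" reversible="false">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>GENE_ASSOCIATION: (YAL012W and YGR155W)</p>
          </body>
        </notes>
        <listOfReactants>
          <speciesReference species="f6p_c" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="prec_c" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="0"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="biomass" name="biomass drain" reversible="false">
        <listOfReactants>
          <speciesReference species="prec_c" stoichiometry="1"/>
        </listOfReactants>
        <kineticLaw>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="1"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
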