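<?xml version="1.0" encoding="UTF-8"?>
<granusim-protocol>
  <world domainWidth="508" domainHeight="508" gridResolution="254" biofilmDiffusivity="0.3" timestep="1" duration="500" seed="42" scenario="reactor" initRegionRadius="15" agitationStrength="5" agitationJitterFrac="0.03" boundaryLayer="40" sliceThickness="2" snapshotEvery="10" shoveK="0.5" shoveThresholdFrac="0.1" adhesionHom="0.5" adhesionHet="0.5" adhesionRangeFrac="0.6" adhesionRangeMin="0.5" relaxTol="0.1" relaxMaxPass="100" solverTol="1e-06" solverMaxIter="50" maxGrowthFrac="0.1" reactorGrowth="false" literalMethaneStoich="false" methanogenStarvesOn="acetate">
    <solute name="glucose" diffusivity="5.8e-06" SBulk="0.175" volatile="false" boundary="bulk"/>
    <solute name="acetate" diffusivity="0.000105" SBulk="0" volatile="false" boundary="noflux"/>
    <solute name="methane" diffusivity="0.000129" SBulk="0" volatile="true" boundary="absorbing"/>
  </world>
  <species name="acidogen" initAreaNumber="100" cellMass="300" epsCapsuleMass="0" divisionRadius="3" muMax="0.208" deathDelay="48" biomassDensity="573" Ks="0.26" Ki="0.1" yieldBiomass="0.3" yieldProduct="0.82" deathThreshold="0.02" substrate="glucose" product="acetate"/>
  <species name="methanogen" initAreaNumber="100" cellMass="1500" epsCapsuleMass="10" divisionRadius="3" muMax="0.1" deathDelay="48" biomassDensity="573" Ks="0.005" yieldBiomass="0.15" yieldProduct="0.26" deathThreshold="1e-05" substrate="acetate" product="methane"/>
  <species name="dead" initAreaNumber="0" cellMass="300" epsCapsuleMass="0" divisionRadius="3" muMax="0" deathDelay="Inf" biomassDensity="573"/>
</granusim-protocol>
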