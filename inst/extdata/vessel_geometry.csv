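vessel,capacity_ml,vessel_diameter_mm,liquid_height_mm,impeller_type,impeller_diameter_mm,flow_pattern
EasyMax,100,51,41.5,RC,30,radial
EasyMax,100,51,41.5,PBT,25,axial
OptiMax,1000,100,81,RC,32,radial
OptiMax,1000,100,81,PBT,45,axial
Miniplant,10000,200,162,RC,110,radial
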