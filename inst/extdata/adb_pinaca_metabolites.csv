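id,rule_sites,formula,mz_printed,rt_min,product_ions
parent,,C19H27FN4O2,363.2191,8.21,145.0396;233.1085;251.1190;318.1976
M1,oh@side_chain+oh@side_chain,C19H27FN4O4,395.2089,5.56,145.0396;163.0502;267.1140;378.1824
M2,f_to_oh@side_chain+oh@side_chain,C19H28N4O4,377.2183,5.62,145.0396;229.0972;247.1077;332.1969;360.1918
M3,f_to_oh@side_chain+oh@adb_residue,C19H28N4O4,377.2183,5.67,145.0396;213.1022;231.1128;360.1918
M4,f_to_oh@side_chain+oh@side_chain,C19H28N4O4,377.2183,5.72,145.0396;229.0972;247.1077;332.1969;360.1918
M5,dehydro@adb_residue+f_to_oh@side_chain+oh@adb_residue,C19H26N4O4,375.2027,5.77,145.0396;213.1022;231.1128;357.1921
M6,f_to_oh@side_chain+oh@core,C19H28N4O4,377.2183,6.05,161.0346;179.0451;229.0972;247.1077;332.1969
M7,dehydro@adb_residue+f_to_oh@side_chain+oh@side_chain,C19H26N4O4,375.2027,6.08,145.0396;229.0972;245.0921;330.1812;358.1761
M8,f_to_cho@side_chain+oh@adb_residue,C19H26N4O4,375.2027,6.30,145.0396;163.0502;201.1022;330.1812;358.1761
M9,dehydro@adb_residue+f_to_oh@side_chain+ox_aldehyde@adb_residue,C19H24N4O4,373.1870,6.38,145.0396;163.0502;213.1022;231.1128
M10,oh@side_chain,C19H27FN4O3,379.2140,6.57,145.0396;231.0928;249.1034;267.1140;334.1925
M11,f_to_cooh@side_chain,C19H26N4O4,375.2027,6.59,145.0396;217.0972;245.0921;330.1812;358.1761
M12,oh@side_chain,C19H27FN4O3,379.2140,6.64,145.0396;231.0928;249.1034;267.1140;334.1925
M13,f_to_oh@side_chain,C19H28N4O3,361.2234,6.66,145.0396;213.1022;231.1128;316.2020;344.1969
M14,oh@side_chain,C19H27FN4O3,379.2140,6.69,145.0396;231.0928;249.1034;267.1140;334.1925
M15,oh@side_chain,C19H27FN4O3,379.2140,6.90,145.0396;231.0928;249.1034;267.1140;334.1925
M16,amide_hydrolysis@adb_residue+dehydro@adb_residue+f_to_oh@side_chain,C19H25N3O4,360.1918,7.08,145.0396;163.0502;213.1021;231.1128;360.1918
M17,oh@side_chain,C19H27FN4O3,379.2140,7.12,145.0396;233.1085;251.1190;362.1874
M18,amide_hydrolysis@adb_residue+f_to_oh@side_chain,C19H27N3O4,362.2074,7.29,145.0396;213.1022;231.1128;316.2020
M19,oh@core,C19H27FN4O3,379.2140,7.42,161.0346;179.0451;249.1034;267.1140;334.1925
M20,amide_hydrolysis@adb_residue+oh@side_chain,C19H26FN3O4,380.1980,7.54,145.0396;251.1190;304.1820;362.1874
M21,deamination@adb_residue+oh@core,C19H26FN3O4,380.1980,8.04,161.0346;179.0451;229.0972;267.1140;334.1925
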