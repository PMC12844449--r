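id,rule_sites,formula,mz_printed,rt_min,product_ions
parent,,C20H28FN3O2,362.2238,7.95,144.0444;232.1132;345.1973
M1,oh@core+oh@side_chain,C20H28FN3O4,394.2137,5.37,160.0393;264.1031;377.1871
M2,f_to_oh@side_chain+oh@core,C20H29N3O4,376.2231,5.39,160.0393;246.1125
M3,oh@core+oh@side_chain,C20H28FN3O4,394.2137,5.49,160.0393;264.1031;377.1871
M4,f_to_oh@side_chain+oh@core,C20H29N3O4,376.2231,5.52,160.0393;246.1125;359.1965
M5,oh@adb_residue+oh@side_chain,C20H28FN3O4,394.2137,5.53,144.0444;248.1081;377.1871
M6,oh@core+oh@side_chain,C20H28FN3O4,394.2137,5.60,160.0393;264.1031;377.1871
M7,f_to_oh@side_chain+oh@side_chain,C20H29N3O4,376.2231,5.61,144.0444;246.1125;359.1965
M8,f_to_oh@side_chain+oh@adb_residue,C20H29N3O4,376.2231,5.66,144.0444;230.1176;359.1965
M9,oh@adb_residue+oh@side_chain,C20H28FN3O4,394.2137,5.69,144.0444;248.1081;377.1871
M10,dehydro@adb_residue+f_to_oh@side_chain+oh@adb_residue,C20H27N3O4,374.2074,5.72,144.0444;230.1176
M11,f_to_oh@side_chain+oh@core,C20H29N3O4,376.2231,5.77,160.0393;246.1125;359.1965
M12,oh@adb_residue+oh@side_chain,C20H28FN3O4,394.2137,5.83,144.0444;248.1081;377.1871
M13,oh@core+oh@side_chain,C20H28FN3O4,394.2137,5.85,160.0393;264.1031;377.1871
M14,n_dealkylation@side_chain,C15H19N3O2,274.1550,5.85,144.0444;229.1335;257.1285
M15,oh@adb_residue+oh@core,C20H28FN3O4,394.2137,6.02,160.0393;248.1031;377.1871
M16,dehydro@adb_residue+f_to_oh@side_chain+ox_aldehyde@adb_residue,C20H25N3O4,372.1918,6.20,144.0444;230.1176
M17,f_to_cooh@side_chain,C20H27N3O4,374.2074,6.47,101.0597;144.0444;244.0968;357.1809
M18,oh@side_chain,C20H28FN3O3,378.2188,6.47,144.0444;248.1081;361.1922
M19,f_to_oh@side_chain,C20H29N3O3,360.2282,6.54,144.0444;230.1176;343.2016
M20,oh@side_chain,C20H28FN3O3,378.2188,6.60,144.0444;248.1081;361.1922
M21,oh@side_chain,C20H28FN3O3,378.2188,6.72,144.0444;248.1081;361.1922
M22,f_to_cho@side_chain,C20H27N3O3,358.2125,6.72,144.0444;228.1019;341.1860
M23,f_to_cho@side_chain,C20H27N3O3,358.2125,6.84,144.0444;228.1019
M24,amide_hydrolysis@adb_residue+dehydro@adb_residue+f_to_oh@side_chain,C20H26N2O4,359.1965,6.86,144.0444;230.1176
M25,oh@core,C20H28FN3O3,378.2188,7.01,160.0393;248.1081;361.1922
M26,oh@adb_residue,C20H28FN3O3,378.2188,7.05,144.0444;232.1132;361.1922
M27,dehydro@adb_residue+oh@adb_residue,C20H26FN3O3,376.2031,7.07,144.0444;232.1132
M28,f_to_cho@side_chain,C20H27N3O3,358.2125,7.16,144.0444;228.1019;341.1860
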