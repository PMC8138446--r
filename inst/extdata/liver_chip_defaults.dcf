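chamber_length_um: 5560
chamber_width_um: 560
cell_chamber_height_um: 100
media_channel_height_um: 100
membrane_thickness_um: 15
membrane_porosity: 0.056
membrane_pore_diameter_um: 3
pdms_slab_thickness_mm: 3.5
flow_rate_ul_per_h: 20
fluid_density_kg_m3: 1000
dynamic_viscosity_mPa_s: 0.78
D_O2_media_m2_s: 3.0e-9
D_O2_pdms_m2_s: 3.25e-9
D_small_molecule_m2_s: 1.0e-9
c_inlet_O2_mol_m3: 0.173
c_sat_pdms_mM: 1.11
VO2max_mol_s_cell: 1.04e-16
Km_mmHg: 5.6
S_cell_mM_atm: 1.049
rho_cell_per_m3: 6.44e13
n_cells: 9812
ambient_O2_fraction: 0.187
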