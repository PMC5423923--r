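# Default synthetic scenario: four clusters of 50 regions, 2003-2043,
# observed regime until 2013, projected regime after. The "east" cluster
# carries 2.5x working-age mortality, a strong mid-century boom wave, a
# pronounced 1990s bust cohort and net out-migration with a 2008 shock;
# migration converges across regions in the projected segment.

[scenario]
start_year = 2003
end_year = 2043
observed_until = 2013
open_age = 100
seed = 1

[[cluster]]
label = "east"
n_regions = 50
noise_sd = 0.08
initial_size = 20000
initial_growth = 0.0
mortality_form = "gompertz"
mortality_a = 6.0e-5
mortality_b = 0.095
mortality_multiplier_working_age = 2.5
fertility_form = "points"
fertility_ages = [12, 18, 25, 33, 42, 50]
fertility_values = [0.0, 0.020, 0.055, 0.035, 0.008, 0.0]
migration_form = "points"
migration_ages = [0, 14, 20, 30, 45, 64, 100]
migration_values = [0.0, -0.001, -0.008, -0.005, -0.002, -0.001, 0.0]
migration_shock_year = 2008
migration_shock_delta = -0.009
migration_convergence_rate = 0.5
wave_from = [1950, 1990]
wave_to = [1980, 1999]
wave_multiplier = [1.30, 0.55]

[[cluster]]
label = "west"
n_regions = 50
noise_sd = 0.08
initial_size = 20000
initial_growth = 0.0
mortality_form = "gompertz"
mortality_a = 6.0e-5
mortality_b = 0.095
mortality_multiplier_working_age = 1.0
fertility_form = "points"
fertility_ages = [12, 18, 25, 33, 42, 50]
fertility_values = [0.0, 0.025, 0.060, 0.040, 0.010, 0.0]
migration_form = "points"
migration_ages = [0, 14, 20, 30, 45, 64, 100]
migration_values = [0.0, 0.001, 0.006, 0.004, 0.001, 0.0, 0.0]
migration_shock_year = 2008
migration_shock_delta = -0.006
migration_convergence_rate = 0.5
wave_from = [1946]
wave_to = [1964]
wave_multiplier = [1.20]

[[cluster]]
label = "south"
n_regions = 50
noise_sd = 0.08
initial_size = 20000
initial_growth = 0.0
mortality_form = "gompertz"
mortality_a = 6.0e-5
mortality_b = 0.095
mortality_multiplier_working_age = 1.0
fertility_form = "points"
fertility_ages = [12, 18, 25, 33, 42, 50]
fertility_values = [0.0, 0.018, 0.050, 0.035, 0.008, 0.0]
migration_form = "points"
migration_ages = [0, 14, 20, 30, 45, 64, 100]
migration_values = [0.0, 0.000, 0.004, 0.002, 0.000, 0.0, 0.0]
migration_shock_year = 2008
migration_shock_delta = -0.014
migration_convergence_rate = 0.5
wave_from = [1955]
wave_to = [1975]
wave_multiplier = [1.15]

[[cluster]]
label = "north"
n_regions = 50
noise_sd = 0.08
initial_size = 20000
initial_growth = 0.0
mortality_form = "gompertz"
mortality_a = 6.0e-5
mortality_b = 0.095
mortality_multiplier_working_age = 1.0
fertility_form = "points"
fertility_ages = [12, 18, 25, 33, 42, 50]
fertility_values = [0.0, 0.030, 0.065, 0.045, 0.012, 0.0]
migration_form = "points"
migration_ages = [0, 14, 20, 30, 45, 64, 100]
migration_values = [0.0, 0.001, 0.004, 0.002, 0.001, 0.0, 0.0]
migration_shock_year = 2008
migration_shock_delta = 0.005
migration_convergence_rate = 0.5
wave_from = [1946]
wave_to = [1960]
wave_multiplier = [1.15]
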