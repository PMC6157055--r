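# Model parameters for the hypertension guideline budget-impact model.
# Schema: globals (scalar settings) + parameters (canonical name ->
# estimate / units / dist / note). Distributions follow the published
# sensitivity-analysis parameterisation: beta {a, b}, poisson {lambda},
# gamma {shape, scale, currency}. Gamma cost distributions are stated on
# the Colombian peso (COP) scale and are converted to USD after sampling.
globals:
  baseline_prevalence: 0.072
  horizon_years: [2018, 2019, 2020]
  cpi_by_year:
    2018: 3.95
    2019: 4.35
    2020: 3.95
  fx_cop_per_usd: 2877
  psa_iterations: 5000
parameters:
  physician_prescription:
    estimate: 0.52
    units: probability
    dist: {kind: beta, a: 29, b: 31}
    note: probability that a physician prescribes per guideline
  adherence_old:
    estimate: 0.45
    units: probability
    dist: {kind: beta, a: 45, b: 55}
    note: patient adherence, established hypertension (BP > 140/90)
  adherence_new:
    estimate: 0.2
    units: probability
    dist: {kind: beta, a: 20, b: 80}
    note: patient adherence, newly classified stratum (130-139/80-89)
  p_ami_standard:
    estimate: 0.0078
    units: annual probability
    dist: {kind: beta, a: 116, b: 4562}
    note: AMI under standard control (BP < 140/90)
  p_stroke_standard:
    estimate: 0.0047
    units: annual probability
    dist: {kind: beta, a: 140, b: 4543}
    note: stroke under standard control
  p_hf_standard:
    estimate: 0.0067
    units: annual probability
    dist: {kind: beta, a: 100, b: 4583}
    note: heart failure under standard control
  p_cvdeath_standard:
    estimate: 0.0043
    units: annual probability
    dist: {kind: beta, a: 65, b: 4618}
    note: cardiovascular death under standard control
  p_ami_intensive:
    estimate: 0.0065
    units: annual probability
    dist: {kind: beta, a: 97, b: 4586}
    note: AMI under intensive control (BP < 120/80)
  p_stroke_intensive:
    estimate: 0.0041
    units: annual probability
    dist: {kind: beta, a: 62, b: 4616}
    note: stroke under intensive control
  p_hf_intensive:
    estimate: 0.0041
    units: annual probability
    dist: {kind: beta, a: 62, b: 4616}
    note: heart failure under intensive control
  p_cvdeath_intensive:
    estimate: 0.0025
    units: annual probability
    dist: {kind: beta, a: 37, b: 4641}
    note: cardiovascular death under intensive control
  p_ami_untreated:
    estimate: 0.047
    units: annual probability
    dist: {kind: beta, a: 47, b: 953}
    note: AMI in untreated patients (calibrated)
  p_stroke_untreated:
    estimate: 0.104
    units: annual probability
    dist: {kind: beta, a: 104, b: 896}
    note: stroke in untreated patients (calibrated)
  p_hf_untreated:
    estimate: 0.0396
    units: annual probability
    dist: {kind: beta, a: 39, b: 961}
    note: heart failure in untreated patients (calibrated)
  tablets_intensive:
    estimate: 2.8
    units: tablets/day
    dist: {kind: poisson, lambda: 2.8}
    note: mean daily tablets, intensive control
  tablets_standard:
    estimate: 1.8
    units: tablets/day
    dist: {kind: poisson, lambda: 1.8}
    note: mean daily tablets, standard control
  diagnostic_frequency:
    estimate: 0.61
    units: panels/year
    dist: {kind: poisson, lambda: 1.5}
    note: mean annual prescription of diagnostic aids
  hf_decompensations:
    estimate: 2.2
    units: episodes/year
    dist: {kind: poisson, lambda: 2}
    note: mean annual decompensation episodes per HF case
  medication_daily_cost:
    estimate: 0.00556
    units: USD per tablet-day
    note: weighted average daily cost of antihypertensive medication
  diagnostics_cost:
    estimate: 57.91
    units: USD per panel
    note: average total cost of diagnostic aids (currency unlabelled in
      the source table; treated as USD, consistent with adjacent rows)
  ami_episode_cost:
    estimate:
      2018: 2938
      2019: 3235
      2020: 2934
    units: USD per episode
    note: average total cost per AMI episode, year-specific; no variance
      data, so not distribution-tagged
  stroke_episode_cost:
    estimate: 3430
    units: USD per episode
    dist: {kind: gamma, shape: 0.44604, scale: 19360084, currency: COP}
    note: average total cost per stroke episode
  hf_decompensation_cost:
    estimate: 1990
    units: USD per episode
    dist: {kind: gamma, shape: 0.44248, scale: 14526853, currency: COP}
    note: hospital cost per decompensated HF episode
  hf_chronic_cost:
    estimate: 1131
    units: USD per year
    dist: {kind: gamma, shape: 0.1599, scale: 1902392, currency: COP}
    note: annual outpatient cost of chronic HF management
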