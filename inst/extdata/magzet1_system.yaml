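# MagZet1 competition system preset.
#
# Dissociation constants are apparent values measured in aqueous buffer
# (50 mM PIPES, 100 mM KCl, pH 7.0); Mg binding at 25 C. Metal totals
# default to zero -- set them per experiment before solving.
components:
- name: MagZet1
  role: sensor
  total: 10
  unit: uM
- name: Mg
  role: metal
  total: 0
  unit: mM
- name: Ca
  role: metal
  total: 0
  unit: mM
- name: Zn
  role: metal
  total: 0
  unit: uM
- name: ATP
  role: ligand
  total: 0
  unit: mM
reactions:
- product: MagZet1.Mg
  stoichiometry: {MagZet1: 1, Mg: 1}
  kd: 0.14          # 0.088 mM at 37 C
  unit: mM
  temperature: 25 C
  medium: 50 mM PIPES, 100 mM KCl, pH 7.0
- product: MagZet1.Ca
  stoichiometry: {MagZet1: 1, Ca: 1}
  kd: 1.7
  unit: mM
  temperature: 25 C
- product: MagZet1.Zn
  stoichiometry: {MagZet1: 1, Zn: 1}
  kd: 2.6
  unit: nM
  temperature: 25 C
- product: Mg.ATP
  stoichiometry: {Mg: 1, ATP: 1}
  kd: 50            # literature MgATP constant
  unit: uM
- product: MagZet1.Mg.ATP
  stoichiometry: {MagZet1: 1, Mg.ATP: 1}   # assembled from sensor + MgATP
  kd: 100
  unit: mM
# Emission-band model. Maxima and the free/Mg-bound brightness follow the
# measured quantum yields (40.4% free, 76% Mg-bound); band widths and the
# Ca-/Zn-bound and protonated brightness are synthetic modeling choices
# (those quantum yields were not determined experimentally).
spectra:
- name: MagZet1
  bands: [{center: 500, width: 34, amplitude: 1}]
  brightness: 0.404
  absorption_max: 490
  emission_max: 500
- name: MagZet1.Mg
  bands: [{center: 530, width: 34, amplitude: 1}]
  brightness: 0.76
  absorption_max: 395
  emission_max: 530
- name: MagZet1.Ca
  bands: [{center: 520, width: 34, amplitude: 1}]
  brightness: 0.40
  absorption_max: 383
  emission_max: 520
- name: MagZet1.Zn
  bands: [{center: 545, width: 34, amplitude: 1}]
  brightness: 0.20
  absorption_max: 410
  emission_max: 545
- name: MagZet1.H
  bands: [{center: 630, width: 40, amplitude: 1}]
  brightness: 0.02
  absorption_max: 480
  emission_max: 630
- name: MagZet1.Mg.ATP
  bands: [{center: 530, width: 34, amplitude: 1}]
  brightness: 0.76
  emission_max: 530
channels:
  excitation: 390
  detect:
  - {name: F500, center: 500, bandwidth: 1}
  - {name: F530, center: 530, bandwidth: 1}
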