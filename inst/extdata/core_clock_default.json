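{
  "description": "Default core-clock parameterization, frozen output of calibrate_default_model: 9-state three-loop network with stoichiometric PER:CRY-BMAL1 sequestration and saturable mRNA decay. Baseline period 23.000 h at ktt = 1; period strictly decreasing over the ktt grid; kt2 x 1.6 reproduces the RAS signature (Cry up, Per down, longer period).",
  "params": {
    "kt1": 3.61457632824315,
    "kt2": 0.541730547276203,
    "kt3": 0.491980304107397,
    "kt4": 0.00689830295202754,
    "kt5": 1.66434012875331,
    "ktt": 1,
    "a": 5,
    "g": 0.0616544883880395,
    "h": 6,
    "r": 1.54477602374469,
    "hb": 8,
    "rb": 0.062237806330413,
    "ab": 8,
    "gb": 1.45410131959751,
    "kp_p": 0.0166807393705549,
    "kp_c": 1.13115657349389,
    "kp_b": 0.665857990993444,
    "k_ass": 0.0919064626427087,
    "dm_p": 1.69148574478151,
    "dm_c": 0.606048630964448,
    "dm_b": 0.574764478989075,
    "d_R": 3.1636255309264,
    "d_Ra": 0.0020465980702984,
    "dp_p": 1.15946165783199,
    "dp_c": 0.179398976612723,
    "dp_b": 0.0197417383534657,
    "d_PC": 0.0758660477559077,
    "k_seq": 0.306732545041963,
    "Km": 0.311468114490905,
    "dummy": 1
  },
  "y0": [10.7849799700837, 0.144791251754489, 0.135506004258381, 2.09327091402859, 0.258207030117819, 0.00308670044454242, 113.311737524827, 0.0124192342199118, 0.089199857261441],
  "state_names": ["P_m", "C_m", "P_c", "C_c", "PC", "R", "R_a", "B_m", "B_p"],
  "calibration": {
    "tau_h": 23,
    "ktt_grid": [0.4, 0.7, 1, 1.3, 1.6],
    "ktt_grid_tau_h": [25.3988, 24.0335, 23, 22.482, 22.1788],
    "bm_relative_amplitude": 0.255,
    "kt2_hit": {
      "factor": 1.6,
      "delta_tau_h": 0.804,
      "dM_Per": -0.555,
      "dM_Cry": 1.5
    }
  }
}
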