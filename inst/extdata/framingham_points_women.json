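{
  "description": "Total-cholesterol-based coronary risk point system for women (Wilson et al., 1998, Circulation 97:1837-1847), transcribed by hand. Categories are left-closed intervals: cuts give the lower bound of each category after the first; points[i] applies to [cuts[i-1], cuts[i]).",
  "sex": "female",
  "age": {
    "domain": [30, 75],
    "cuts": [35, 40, 45, 50, 55, 60, 65, 70],
    "points": [-9, -4, 0, 3, 6, 7, 8, 8, 8],
    "units": "years"
  },
  "total_cholesterol": {
    "domain": [1, 1000],
    "cuts": [160, 200, 240, 280],
    "points": [-2, 0, 1, 2, 3],
    "units": "mg/dL"
  },
  "hdl": {
    "domain": [1, 1000],
    "cuts": [35, 45, 50, 60],
    "points": [5, 2, 1, 0, -3],
    "units": "mg/dL"
  },
  "blood_pressure": {
    "sbp_domain": [1, 400],
    "dbp_domain": [1, 300],
    "sbp_cuts": [120, 130, 140, 160],
    "dbp_cuts": [80, 85, 90, 100],
    "points": [-3, 0, 0, 2, 3],
    "discordance": "higher-risk category governs the joint cell",
    "units": "mm Hg"
  },
  "smoker_points": 2,
  "diabetes_points": 4
}
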