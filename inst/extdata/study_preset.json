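{
  "description": "Synthetic-cohort calibration: published group-level mean percent scores (divided by 100) for each preference group, speech material, environment, presentation level and IIDR setting. Noise conditions are at +10 dB SNR.",
  "n_per_group": {"preCSPL65": 5, "preCSPL80": 6},
  "subject_sd": 0.2,
  "accuracy": [
    {"group": "preCSPL65", "material": "word",     "environment": "quiet", "level_db_spl": 65, "iidr": "default", "p": 0.928},
    {"group": "preCSPL65", "material": "word",     "environment": "noise", "level_db_spl": 65, "iidr": "default", "p": 0.704},
    {"group": "preCSPL65", "material": "sentence", "environment": "quiet", "level_db_spl": 65, "iidr": "default", "p": 0.970},
    {"group": "preCSPL65", "material": "sentence", "environment": "noise", "level_db_spl": 65, "iidr": "default", "p": 0.834},
    {"group": "preCSPL65", "material": "word",     "environment": "quiet", "level_db_spl": 80, "iidr": "default", "p": 0.840},
    {"group": "preCSPL65", "material": "word",     "environment": "noise", "level_db_spl": 80, "iidr": "default", "p": 0.296},
    {"group": "preCSPL65", "material": "sentence", "environment": "quiet", "level_db_spl": 80, "iidr": "default", "p": 0.810},
    {"group": "preCSPL65", "material": "sentence", "environment": "noise", "level_db_spl": 80, "iidr": "default", "p": 0.446},
    {"group": "preCSPL65", "material": "word",     "environment": "quiet", "level_db_spl": 65, "iidr": "wide",    "p": 0.968},
    {"group": "preCSPL65", "material": "word",     "environment": "noise", "level_db_spl": 65, "iidr": "wide",    "p": 0.776},
    {"group": "preCSPL65", "material": "sentence", "environment": "quiet", "level_db_spl": 65, "iidr": "wide",    "p": 0.948},
    {"group": "preCSPL65", "material": "sentence", "environment": "noise", "level_db_spl": 65, "iidr": "wide",    "p": 0.866},
    {"group": "preCSPL65", "material": "word",     "environment": "quiet", "level_db_spl": 80, "iidr": "wide",    "p": 0.752},
    {"group": "preCSPL65", "material": "word",     "environment": "noise", "level_db_spl": 80, "iidr": "wide",    "p": 0.448},
    {"group": "preCSPL65", "material": "sentence", "environment": "quiet", "level_db_spl": 80, "iidr": "wide",    "p": 0.912},
    {"group": "preCSPL65", "material": "sentence", "environment": "noise", "level_db_spl": 80, "iidr": "wide",    "p": 0.578},
    {"group": "preCSPL80", "material": "word",     "environment": "quiet", "level_db_spl": 65, "iidr": "default", "p": 0.673},
    {"group": "preCSPL80", "material": "word",     "environment": "noise", "level_db_spl": 65, "iidr": "default", "p": 0.166},
    {"group": "preCSPL80", "material": "sentence", "environment": "quiet", "level_db_spl": 65, "iidr": "default", "p": 0.783},
    {"group": "preCSPL80", "material": "sentence", "environment": "noise", "level_db_spl": 65, "iidr": "default", "p": 0.250},
    {"group": "preCSPL80", "material": "word",     "environment": "quiet", "level_db_spl": 80, "iidr": "default", "p": 0.460},
    {"group": "preCSPL80", "material": "word",     "environment": "noise", "level_db_spl": 80, "iidr": "default", "p": 0.007},
    {"group": "preCSPL80", "material": "sentence", "environment": "quiet", "level_db_spl": 80, "iidr": "default", "p": 0.563},
    {"group": "preCSPL80", "material": "sentence", "environment": "noise", "level_db_spl": 80, "iidr": "default", "p": 0.032},
    {"group": "preCSPL80", "material": "word",     "environment": "quiet", "level_db_spl": 65, "iidr": "wide",    "p": 0.767},
    {"group": "preCSPL80", "material": "word",     "environment": "noise", "level_db_spl": 65, "iidr": "wide",    "p": 0.407},
    {"group": "preCSPL80", "material": "sentence", "environment": "quiet", "level_db_spl": 65, "iidr": "wide",    "p": 0.835},
    {"group": "preCSPL80", "material": "sentence", "environment": "noise", "level_db_spl": 65, "iidr": "wide",    "p": 0.578},
    {"group": "preCSPL80", "material": "word",     "environment": "quiet", "level_db_spl": 80, "iidr": "wide",    "p": 0.707},
    {"group": "preCSPL80", "material": "word",     "environment": "noise", "level_db_spl": 80, "iidr": "wide",    "p": 0.313},
    {"group": "preCSPL80", "material": "sentence", "environment": "quiet", "level_db_spl": 80, "iidr": "wide",    "p": 0.755},
    {"group": "preCSPL80", "material": "sentence", "environment": "noise", "level_db_spl": 80, "iidr": "wide",    "p": 0.458}
  ]
}
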