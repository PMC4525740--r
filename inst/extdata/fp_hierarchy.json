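{
  "goal": "Choosing a family physician",
  "criteria": [
    "Individual Characteristics",
    "Patient-Doctor relationship",
    "Professional Characteristics",
    "The Setting",
    "Ethical Characteristics"
  ],
  "descriptions": {
    "Individual Characteristics": "Personal manner of the physician: smiling, gentle, polite, respectful, understanding, calm, friendly.",
    "Patient-Doctor relationship": "Closeness and communication: makes the patient feel valued, listens, informs, knows the family, mutual acquaintance.",
    "Professional Characteristics": "Clinical competence: history taking, knowledge, experience, diagnosis and treatment without referral, trustworthy prescribing and reporting.",
    "The Setting": "Organisation of care: not crowded, short waits, good queuing, continuity with a single doctor.",
    "Ethical Characteristics": "Professional ethics: no discrimination, acts in emergencies, writes reports when needed, not distracted by commercial interests."
  },
  "threshold": 0.10,
  "method": "eigenvector"
}
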