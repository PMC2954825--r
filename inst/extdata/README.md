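# External assets (not shipped)

Two optional asset sets unlock the exact published-score reproductions in
the acceptance suite; both require network access and are therefore not
bundled:

- `maxent/me2x5` — the published 5' maximum-entropy splice-site table
  (16384 numeric values, one per line), as distributed with the original
  maximum-entropy splice scorer. Used by `maxent_donor_model()`.
- `transcripts/AY028805.1.fa`, `transcripts/AB163917.1.fa` — the two
  public mRNA records (truncated and canonical splice forms) in FASTA.
  Used by `translate_transcript()`.

Without them the package falls back to the built-in toy PWM donor model
and the synthetic gene fixture, and the corresponding acceptance tests
fail with an explanatory message.
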