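# toy12.vcf

Hand-written 12-record VCF used to pin down the site filter
(keep a record iff DP >= 8 AND at least one alternate allele has
AD/DP >= 0.10; alternates individually below 10% are pruned from the
record; records with missing DP/AD are rejected and counted).

Per-record expectation:

| POS  | DP  | AD        | alt fraction(s) | outcome |
|------|-----|-----------|-----------------|---------|
| 100  | 7   | 3,4       | 0.571           | excluded: DP 7 < 8 |
| 200  | 10  | 9,1       | 0.100           | kept: 10% boundary is inclusive |
| 300  | 100 | 95,5      | 0.050           | excluded: alt below 10% |
| 400  | 40  | 20,20     | 0.500           | kept |
| 500  | 30  | 20,10     | 0.333           | kept |
| 600  | 50  | 48,2      | 0.040           | excluded |
| 700  | 30  | 18,10,2   | 0.333, 0.067    | kept; second alt (C) pruned |
| 800  | 8   | 7,1       | 0.125           | kept: DP 8 boundary is inclusive |
| 900  | 20  | 15,5      | 0.250           | kept (insertion) |
| 1000 | 20  | 16,4      | 0.200           | kept (deletion) |
| 1100 | .   | .         | -               | rejected: missing DP/AD (warned, counted) |
| 1200 | 20  | 19,1      | 0.050           | excluded |

Survivors: positions 200, 400, 500, 700, 800, 900, 1000 (7 records);
record 700 keeps only its first alternate (T). One record (1100) counts
toward the missing-field rejection tally.
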