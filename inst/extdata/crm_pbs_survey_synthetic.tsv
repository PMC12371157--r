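# CRM autonomy x PBS-motif survey. Class marginals (169 of 189 autonomous
# and 374 of 482 nonautonomous elements PBS-positive; 449 of the 543
# detected in the four dominant motif groups) follow the published hop CRM
# survey; the per-motif split within each class is a synthetic,
# marginal-consistent breakdown.
autonomy	pbs	count
autonomous	PBS1	60
autonomous	PBS2	45
autonomous	PBS3	30
autonomous	PBS4	20
autonomous	PBS5	8
autonomous	PBS6	6
autonomous	none	20
nonautonomous	PBS4	180
nonautonomous	PBS1	50
nonautonomous	PBS2	35
nonautonomous	PBS3	29
nonautonomous	PBS5	40
nonautonomous	PBS6	40
nonautonomous	none	108
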