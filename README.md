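# mtmap

Merged transition maps for combinatorial drug-target discovery in
asynchronous Boolean networks.

## The problem

Cancer cells respond heterogeneously to a single targeted drug: after
the drug fixes ("pins") its target molecule ON or OFF, the regulatory
network drifts stochastically and different cells settle into
different stable states (attractors), some of them drug-resistant.
This adaptive resistance arises when the perturbation drives two
multi-stable motifs — self-sustaining positive-feedback units — into
conflicting states, and the conflict is resolved at random by the
asynchronous update order.  The nodes that mediate the conflict flip
their state unusually often along the unwanted transition paths, and
pinning such an *interconnecting node* in the right direction, in
combination with the original drug, can remove the resistant outcome
entirely.

`mtmap` identifies those synergistic partner targets.  For a Boolean
network *N*, a pinned target *T* and phenotype markers it builds the
**merged transition map (MTM)**: the union of state-transition
segments from every original attractor into the *T*-regulated
attractor landscape (drug onset) and from every regulated attractor
back after unpinning (drug withdrawal).  Each segment is factorised by
absorbing-Markov-chain analysis into path ensembles with absorption
probability *p*, conditional expected per-node flip counts
*E[f&#8345;|e]*, a phenotypic-preference sign *pp* (desired +1 /
undesired −1), a transition-type sign (regulated +1 / reversal −1)
and a significance *s* (the source attractor's basin fraction).
Candidate partners are ranked by the weighted flipping frequency

    wff(n) = Σₑ  sₑ · pₑ · E[fₙ|e] · ppₑ · typeₑ

and the pin direction for a partner is chosen by signal-flow analysis
on the signed interaction graph: a candidate driven towards ON by the
drug is pinned OFF, and vice versa.  Comparator baselines (exhaustive
two-node perturbation screening, minimum feedback vertex sets),
attractor identification by constant-node reduction, Monte Carlo basin
estimation, multi-stable motif and interconnecting-node detection, a
conflict-motif census with degree-preserving network randomisation,
and seeded synthetic fixture generators are included.

## Worked example

The shipped conflict fixture is an eight-node network in which the
perturbation input `P` drives a "yellow" motif (`Y1`, `Y2`; desired
marker `M`) and a "green" motif (`G1`, `G2`; resistance marker `R`)
that fight through the interconnecting relay `I1`:

```r
library(mtmap)
fx <- make_conflict_network()
report <- run_pipeline(fx$net, target = "P", type = "ON",
                       spec = fx$phenotype, n_samples = 10000,
                       seed = 42, sps_check = TRUE)
report
#> MTM synergistic-target report
#>   given target: P (ON)
#>   original attractors:
#>   id  kind n_states basin_fraction preference    state
#> 1 A1 point        1      0.2034815        0.0 00000000
#> 2 A2 point        1      0.2472150       -0.5 00011101
#> 3 A3 point        1      0.5493035        0.5 01100010
#>   regulated attractors:
#>   id  kind n_states basin_fraction preference    state
#> 1 A1 point        1      0.4953704       -0.5 11011101
#> 2 A2 point        1      0.5046296        0.5 11110010
#>   ranked synergistic partners:
#>   node      score         wff control_type
#> 1   I1 0.31268622 -0.31268622          OFF
#> 2   G2 0.27877264 -0.27877264          OFF
#> 3   G1 0.19681481 -0.19681481          OFF
#> 4   Y2 0.14311830 -0.14311830           ON
#> 5   Y1 0.05087038  0.05087038          OFF
#>   SPS optimum: G1 (OFF), effectiveness 0.3490
```

Reading the output: untreated, the network rests in three attractors
(all-off, resistant green-win with preference −0.5, desired yellow-win
with +0.5).  Pinning `P = 1` alone leaves a heterogeneous response —
the treated landscape splits roughly 50/50 between the desired
attractor (`M = 1`, preference +0.5) and the resistant one (`R = 1`,
−0.5).  The MTM ranks the interconnecting relay `I1` first (largest
weighted flipping magnitude, carried by the undesired paths — hence
the negative sign) and assigns it control type OFF.  That pair matches
the exhaustive screen's optimum (0.3490 is the tie shared by `I1`/OFF,
`G1`/OFF, `G2`/OFF and `Y2`/ON), and adding the partner rescues the
drug:

```r
control_effectiveness(fx$net, perturbation(P = 1, I1 = 0),
                      fx$phenotype, baseline = perturbation(P = 1))
#> <control assessment: P=1, I1=0: effectiveness +0.4954 (0.0046 -> 0.5000)>
```

The combination collapses the treated landscape to the single desired
attractor (basin-weighted preference 0.50), where the drug alone
achieves 0.0046.

A thin command-line front end is installed under
`inst/cli/mtm.R` (subcommands `attractors`, `run`, `sps`, `motifs`,
`randomize`, `fixture`).

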