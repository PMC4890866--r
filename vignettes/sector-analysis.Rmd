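---
title: "Statistical coupling analysis and protein sectors with protsca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical coupling analysis and protein sectors with protsca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protsca)
```

## The model

Statistical coupling analysis (SCA) asks which groups of amino-acid
positions in a protein family evolve together. Its premise is that the
functionally important covariation is the *conserved* covariation:
raw pairwise covariances in an alignment are dominated by phylogenetic
history and finite sampling, so SCA weights them by how conserved the
underlying amino acids are before looking for collective structure.

Given an alignment of $M$ sequences by $L$ positions, encoded as a
binary array $x_{sia}$ ($a$ = 1..20 amino acids, gaps all-zero), the
chain of quantities is:

1. **Conservation.** The frequency $f_i^a$ of amino acid $a$ at
   position $i$ is compared with a background distribution $q^a$
   through the Kullback–Leibler relative entropy
   $D_i^a = f\ln(f/q) + (1-f)\ln\!\big((1-f)/(1-q)\big)$ (in nats; the
   gradient identity below only holds in natural log). An overall
   positional conservation $D_i$ sums the analogous terms over all 21
   states against a gap-adjusted background
   $\bar q^a = (1-\bar q_0)\,q^a$.
2. **Weighted covariance.** The raw covariance
   $C_{ij}^{ab} = f_{ij}^{ab} - f_i^a f_j^b$ is weighted by the
   conservation gradients
   $\phi_i^a = \partial D_i^a/\partial f_i^a =
   \ln\!\big(f(1-q)/((1-f)q)\big)$, giving
   $\tilde C_{ij}^{ab} = \phi_i^a \phi_j^b\, C_{ij}^{ab}$. The
   $\phi$ weights vanish at $f = q$ and rise steeply toward $f \to 1$:
   unconserved covariation is damped, conserved covariation
   emphasized. They are kept signed (negative below background).
3. **Compression.** Each $20\times20$ block is collapsed to a scalar,
   by default its Frobenius norm
   $\tilde C_{ij} = \big(\sum_{ab} (\tilde C_{ij}^{ab})^2\big)^{1/2}$;
   the spectral norm (top singular value) is available as an
   alternative, justified by the strong dominance of the first
   singular value of these blocks (a property the test suite checks
   on planted data).
4. **Decomposition.** $\tilde C = \tilde V \tilde\Delta \tilde V^\top$.
   Significance of the top eigenmodes is judged against a null built
   by independently permuting the residues within each alignment
   column, which exactly preserves per-column compositions while
   destroying positional correlations. The cutoff is the mean of the
   *second* null eigenvalue plus two standard deviations over trials
   (default 10); the first null eigenvalue is a trivial consequence of
   retained per-column conservation and is ignored when placing the
   cutoff. $k^*$ counts actual eigenvalues above the cutoff.
5. **ICA.** The $k^*$ eigenmodes are rotated into maximally
   independent components $\tilde V^p = W \tilde V_{1..k^*}$:
   decorrelation alone does not isolate coevolving groups, which
   typically emerge along *combinations* of eigenmodes.
6. **Sequence mapping.** The alignment is reduced to an $M \times L$
   matrix $x_{si} = \sum_a \bar P_i^a x_{sia}$ with
   $\bar P_i^a \propto \phi_i^a f_i^a$ (unit rows), and sequences are
   mapped onto the positional modes by
   $\tilde U = x \tilde V \tilde\Delta^{-1/2}$ and
   $\tilde U^p = \tilde U W^\top$, connecting coevolving position
   groups to sequence subfamilies.
7. **Sectors.** Each IC is fitted with a location-scale
   t-distribution (maximum likelihood, df bounded at 1); positions
   above the 95% CDF on the sign-oriented positive tail define the
   IC's position set. The $\tilde C$ submatrix over these sets,
   ordered IC by IC, exposes inter-IC coupling; ICs linked by coupling
   above a threshold (default 0.25) are merged transitively into
   sectors. Sector identification is explicitly heuristic — the
   automatic grouping has a manual override, and the grouping mode is
   recorded in the output.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `pos_gap_cutoff` | 0.4 | raw per-column gap fraction above which a column is truncated (when no reference is given) |
| `seq_gap_cutoff` | 0.2 | per-sequence gap fraction above which a sequence is removed |
| `min_ref_identity` | 0.2 | minimum fractional identity to the reference sequence |
| `weight_identity_threshold` | 0.8 | identity above which sequences share a weight neighborhood; $w_s = 1/\#\{r: S_{rs} > 0.8\}$, $M' = \sum_s w_s$ |
| `weighted_pos_gap_cutoff` | 0.2 | weighted gap frequency above which a column is truncated |
| `lambda` | 0.03 | frequency regularizer; single-site pseudocount $\lambda/21$, pairwise $\lambda/21^2$ |
| `resample_factor` | 1.5 | optional weighted subsample size as a multiple of $M'$ |
| `n_trials` | 10 | randomization trials for the null spectrum |
| `cdf_cutoff` | 0.95 | t-CDF cutoff for IC position selection |
| `group_threshold` | 0.25 | inter-IC coupling above which ICs merge into one sector |

Fractional identity counts matching amino acids over the *full*
alignment length, with gap–gap columns not counted as matches. Under
this convention the self-identity of a gapped row is below 1, so the
weight computation pins $S_{ss} = 1$ explicitly: every sequence
belongs to its own neighborhood, and a sequence with no close
neighbor gets weight exactly 1.

## The synthetic test bed

The generator (`planted_spec()` / `generate_alignment()`) emulates the
statistical structure SCA targets, with serialized ground truth:

- **position-specific conservation**: a stated fraction of
  near-invariant positions (preferred residue shown with probability
  0.9 by default) among otherwise neutral positions drawn i.i.d. from
  the background;
- **planted sectors**: for each sector, every sequence draws a latent
  Bernoulli on/off state (p = 0.5 by default); when "on", each sector
  position shows its preferred residue with probability $\rho$,
  yielding group-level co-conservation. A latent-state model was
  chosen over pairwise Potts sampling because SCA's target signal is
  collective co-conservation, not pair contacts; a Potts generator
  could be added behind the same spec;
- **subfamily structure**: swap maps replace the preferred residue at
  a stated subset of sector positions in one subfamily, splitting a
  sector across clades;
- **redundancy**: appended duplicate copies, optionally mutated.

What the generator does *not* emulate: tree-like phylogenetic
correlation (sequences are exchangeable given subfamily and latent
state), indels beyond uniform gaps, and realistic per-family
background composition. A green recovery test therefore establishes
that the chain of estimators recovers planted co-conservation at
realistic depth and coupling — not that sector calls on any real
family are biologically correct.

## Numerical choices and behaviors worth knowing

- **The collective conservation mode.** Frobenius compression is
  nonnegative, so sampling noise between conserved, *uncorrelated*
  positions rectifies into systematically positive entries: any
  alignment has a collective top mode of this origin, which is exactly
  why the null's first eigenvalue is ignored when placing the cutoff.
  Its in-spectrum analog, however, usually clears the
  second-eigenvalue cutoff. Two consequences, both visible in the
  test suite: a pure-noise alignment typically yields $k^* = 1$ (not
  0 — the $k^*=0$ early exit exists and is tested, but rarely occurs
  naturally), and on synthetic data with near-invariant background
  positions one IC collects those positions as an extra "sector".
  On real families, where strongly conserved positions are usually
  genuinely coupled, this mode carries real signal; on synthetic
  nulls it is a known artifact to read with that understanding.
- **Gap background floor.** Regularized frequencies put mass
  $\lambda/21$ on the gap state even in gap-free alignments, so the
  gap background inside $D_i$ is floored at $\lambda/21$ to keep
  $D_i$ finite; `background()` itself reports the true weighted gap
  fraction (0 when gap-free).
- **Gap state scope.** Single-site frequencies run over 21 states;
  the coevolution tensor, $\phi$, $D_i^a$ and the Frobenius sum run
  over the 20 amino acids only; only $D_i$ uses all 21.
- **ICA.** Infomax natural gradient with a logistic score
  ($\equiv \tanh(u/2)$), learning rate 0.1, tolerance $10^{-7}$ on
  the relative update norm, identity initialization (deterministic;
  the seed is recorded for provenance). ICA operates on the raw
  eigenvectors, not eigenvalue-scaled modes. ICs are sign-oriented
  (largest-magnitude loading positive) and ordered by dominant
  eigenmode, ties broken by descending excess kurtosis.
- **One-sided selection.** The CDF cutoff is applied to the positive
  tail of the oriented IC only: orientation makes the contributing
  group positive. On fit failure the empirical quantile is used, with
  a warning and a `fallback` flag.
- **Overlap resolution.** A position passing the cutoff on several
  ICs goes to the IC with the larger $|$loading$|$; ties to the lower
  IC index.
- **Inter-IC coupling statistic.** The mean off-diagonal block of the
  sector submatrix, normalized by the geometric mean of the
  within-group (off-diagonal) means; singletons fall back to their
  diagonal entry, flagged. The statistic itself is an artifact choice
  (the source method judges "near-independence" visually); the 0.25
  grouping threshold is likewise a default with a manual override.
- **Resampling** is without replacement (selection probability
  proportional to weight), so duplicate rows cannot re-inflate
  correlations; the effective sequence count of the sample may
  slightly exceed $M'$.
- **Hierarchy detectability.** A subfamily-split sector is recovered
  as multiple ICs only when the split contrast mode clears the null
  cutoff. From the block-eigenvalue arithmetic (and confirmed in
  tests), a 10-position sector split 5/5 at $\rho = 0.9$, $M = 500$
  does not produce a significant contrast mode, while a 16-position
  sector split 8/8 does; the packaged hierarchy test world uses the
  latter.
- **Sequence-space decorrelation** ($\tilde U^\top \tilde U$
  diagonal) is exact when the decomposed matrix is the Gram matrix of
  the reduced alignment, and only approximate for the SCA matrix
  $\tilde C$; the property test uses the exact construction.

## Limitations

- Sequence weighting is the simple identity-neighborhood rule; no
  phylogeny-aware reweighting.
- The background table is a fixed database-wide composition;
  `background(..., mode = "alignment")` is available but changes the
  meaning of "conservation".
- Sector grouping automates a judgement the method's authors left to
  the practitioner; treat `sector_assignments` as a starting point
  and use the `manual` override where inter-IC structure is
  ambiguous.
- Validation against published PFAM 27.0 position counts requires the
  original full alignments, which are not redistributable here; the
  acceptance test encodes the expected numbers and runs when the
  files are supplied.

## A worked run

```{r example, eval = FALSE}
set.seed(1)
gen <- generate_alignment(planted_spec(seed = 1))   # M=500, L=100,
                                                    # two 10-position sectors
res <- run_sca(gen$msa, sca_config(seed = 1))
res$summary$k_star          # number of significant eigenmodes
res$summary$sector_sizes    # positions per reported sector
sector_positions(res$sectors)[[1]][, c("ic", "label", "loading")]
write_bundle(res, "sca_out")
```
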