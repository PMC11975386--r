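---
title: "Pore dilation and molecular transport through the NPC: model and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pore dilation and molecular transport through the NPC: model and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcflux)
```

## The scientific problem

The nuclear pore complex (NPC) is a channel through the nuclear envelope
whose interior is filled with intrinsically disordered FG-nucleoporins
(FG-Nups). The pore can dilate and constrict in response to membrane
tension, and the question this package addresses is quantitative: *how does
the transport rate of a molecule of diameter* $d$ *change with the pore
diameter* $D$?

`npcflux` implements two coupled layers:

1. **A polymer-scaling model** that reduces the question to one
   dimensionless master curve, and
2. **a coarse-grained Brownian-dynamics simulator** of the pore — anchored
   bead-spring chains with sticker/spacer binding kinetics and a rigid
   spherical cargo — whose forward-flux-sampling transport rates provide
   the data the model is fitted to.

## The scaling model

Each FG-Nup is treated as a homopolymer with end-to-end distance
$R = b N^\nu$ ($b$ the Kuhn length, $N$ the number of segments, $\nu$ the
Flory exponent; $\nu > 1/2$ in a good solvent). Above the overlap
concentration the chains interpenetrate and form a mesh with correlation
length

$$\xi = b\,\varphi^{-\nu/(3\nu-1)}, \qquad \varphi = \frac{A N}{D^2},
\qquad A = \frac{4 v_{\mathrm{mon}} n_{FG}}{\pi h},$$

where $\varphi$ is the chain volume fraction in a pore of diameter $D$ and
height $h$ holding $n_{FG}$ chains of monomer volume $v_{\mathrm{mon}}$.
The overlap condition $\xi = \xi^* = bN^\nu$ defines the reference scales
$\varphi^* = N^{1-3\nu}$ and $D^* = A^{1/2} N^{3\nu/2}$; in normalized form
$\xi/\xi^* = (D/D^*)^{2\nu/(3\nu-1)}$. With the standard parameter set
($b = \sigma = 0.86$ nm, $\nu = 0.588$, $v_{\mathrm{mon}} = \pi\sigma^3/6$,
$n_{FG} = 80$, $h = 40$ nm) the model gives $D^* \approx 102$ nm for
$N = 209$, comfortably above the physiological pore range of 40–60 nm, and
mesh sizes of 4.7–8.7 nm across that range:

```{r scales}
p <- polymer_params(N = 209)
reference_scales(p)
mesh_size(c(40, 60), p)
```

Inserting a cargo of diameter $d$ into the mesh costs free energy
$\Delta G / k_BT = \gamma (d/\xi)^{(3\nu-1)/\nu}$, with $\gamma$ a single
dimensionless coefficient absorbing mesh interactions and cargo geometry.
An Arrhenius argument ($k_{AB} = k_0 e^{-\Delta G / k_BT}$, insertion
dominating over in-pore diffusion) then yields the master curve

$$\tilde k_{AB} = \exp(-\gamma\, \tilde d^{\alpha} \tilde D^{-2})
 = f(x) = \exp(-\gamma / x^2),$$

with $\tilde d = d/\xi^*$, $\tilde D = D/D^*$,
$\alpha = (3\nu - 1)/\nu$ and $x = \tilde D / \tilde d^{\alpha/2}$. The
derivative $f'(x)$ peaks at $x_0 = \sqrt{2\gamma/3}$: pores near $x_0$
convert small dilations into the largest change in flux
(`peak_sensitivity()`). Fitting $\log k$ against
$u = \tilde d^\alpha \tilde D^{-2}$ by ordinary least squares
(`fit_gamma_k0()`) recovers $\gamma$ (slope) and $k_0$ (intercept); points
with zero measured rate carry no log-scale information and are dropped with
a message. The complementary open-pore regime above $D^*$, where transport
scales with the FG-free hole area as $(D - D_0 - d)^2$, is provided for
comparison as `quadratic_pore_model()`; this package's model targets
$D < D^*$.

## The simulator

### Geometry, chains, force field

The simulation box ($100 \times 100 \times 200$ nm by default) is periodic
in all axes; a hard slab of thickness $h$ at mid-height carries a
cylindrical pore of diameter $D$. $n_{FG}$ bead-spring chains of $N$ beads
(diameter $\sigma$) are anchored on the pore wall on rings spread evenly
over the pore height and staggered azimuthally (8 rings of 10 at the
standard 80 chains); every fourth bead is a sticker (one sticker after
three spacers; the anchored bead is a spacer). Interactions, in reduced
units ($\sigma = 1$, $\Delta t = 1$, $k_BT = 1$):

* bonds $U = k_b (r - r_{eq})^2$ with $k_b = 100$, $r_{eq} = 1$;
* bending $U = k_a\{1 - \cos(\theta - \theta_{eq})\}$ with $k_a = 0.5$,
  $\theta_{eq} = \pi$;
* steric repulsion $U = \epsilon_r e^{-r/\sigma_r}$ ($\epsilon_r = 400$,
  $\sigma_r = 1$) truncated at $r_{cri} = 1$, applied between all bead
  pairs (the reported pair energy is shifted to zero at the cutoff so the
  logged energy is continuous; forces are unaffected);
* a constant outward force $F_{wall} = 400$ on any bead center within
  $\sigma/2$ of a hard surface, directed along the normal from the nearest
  point of the solid (the rim of the pore resolves to the nearest-feature
  normal);
* overdamped Langevin dynamics $\zeta \dot r = -\partial U/\partial r +
  \Lambda$ with per-bead Stokes friction $\zeta = 3\pi\eta\sigma$,
  $\eta = 37.1$ (5.0 cP in physical units), integrated by Euler–Maruyama
  with Gaussian noise of variance $2\zeta k_BT$ per unit time.

### Sticker kinetics

Stickers follow a three-state machine: free-outside (FO, no other sticker
within $r_{thre} = 2\sigma$), free-inside (FI, at least one) and bound (B).
FO$\leftrightarrow$FI transitions are purely diffusive; FI$\to$B and
B$\to$FI are Monte Carlo draws at per-step rates $k_{on} = 2\times10^{-3}$
and $k_{off} = 2\times10^{-4}$. Binding is drawn once per eligible FI–FI
pair per step, so an isolated pair binds with mean waiting time
$1/k_{on} = 500$ steps and unbinds after $1/k_{off} = 5000$ steps
(100 ns) on average — the parameterization under which the off-rate,
converted to physical units with the assumed diffusion-limited on-rate of
$10^9\,\mathrm{M^{-1}s^{-1}}$, corresponds to a dissociation constant of
10 mM (`effective_dissociation_constant()`), in the range of weak
transport-receptor/FG interactions. Bound stickers are exclusive (the
partner map is an involution), attract each other with a constant force
$F_{FG} = 2\,k_BT/\sigma$, and FO$\leftrightarrow$B transitions never
occur. Per step the order is: move, reclassify, unbinding draws, binding
draws. Two details the underlying description leaves open were fixed as
follows: a free sticker with *exactly one* neighbour within $r_{thre}$
counts as FI (FI is the complement of FO, which partitions the free
states); and bound stickers count as neighbours when classifying others
(configurable via `bound_neighbor`). A bound pair separated beyond
$r_{thre}$ stays bound until its $k_{off}$ draw fires; the constant
attraction opposes such excursions.

### Rigid cargo

The cargo is a rigid sphere of diameter $d$ whose surface is discretized
into beads on a Fibonacci lattice at one bead per $\sigma^2$ (so
$\approx \pi (d/\sigma)^2$ beads; a cargo with $d \le \sigma$ degenerates
to a single site). A spherical cap of area $S$ around the body-frame pole
can be flagged as stickers ($S^* = 4\pi$ nm$^2$ is the reference patch);
cargo stickers obey exactly the same state machine as chain stickers.
Surface-bead forces (steric, wall, sticker) are aggregated into a net force
and torque; the center translates with Stokes friction
$\zeta_t = 3\pi\eta d$ and the orientation — a unit quaternion, rotated
exactly and renormalized each step — diffuses with rotational friction
$\zeta_r = \pi\eta d^3$. These mobility choices are the Stokes/
Stokes–Einstein–Debye forms for a sphere; the tests verify the implied
Einstein relation and the orientation decorrelation
$\langle u(0)\cdot u(t)\rangle = e^{-2 D_r t}$.

### Forward flux sampling

Transport is a rare event, so rates are computed by forward flux sampling.
The order parameter is the cargo center's staged progress: the first
interface $I_0$ is a hemisphere of radius $D/2$ over the pore entrance;
basin A is the entry side outside it. The pore is cut into $n_{FFS}$ equal
cylindrical slabs (8 by default), whose exit planes form $I_1..I_{n}$;
commitment to basin B is a matching hemisphere beyond the exit, giving
$n_{FFS}+1$ transition probabilities. The flux phase measures
$\Phi_0$ — first crossings of $I_0$ per unit time spent on the A side,
re-armed only after a full return to A — and stores a complete system
snapshot (chains, sticker registry, cargo pose) at each crossing. Each
interface phase launches trials from uniformly resampled snapshots with
independent derived RNG streams; a trial succeeds on reaching the next
interface and fails on returning to basin A, so backward in-pore
excursions are retained with their natural statistical weight. The full
rate is $k_{AB} = \Phi_0 \prod_i P_{trans,i}$ and the partial rate
$k'_{AB} = \Phi_0 P_{trans,0}$ — a cheap proxy that tracks the full rate
because the insertion step dominates the barrier.

Numerical choices worth stating:

* **A-side time normalization.** $\Phi_0$ divides crossings by time spent
  on the A side of the barrier (tracked by a basin label), not raw
  wall-clock phase time. For barrier-dominated systems the two coincide;
  on shallow-barrier validation toys only this convention makes
  $\Phi_0\prod P_i$ agree with the brute-force rate.
* **Hysteresis buffer.** The basin-A boundary used for re-arming the flux
  counter and failing trials sits one bead diameter outside $I_0$
  (`arm_buffer`). Without it, single-step dithering on the interface
  produces bursty, badly-conditioned crossing counts; with it the counted
  crossings are genuine excursions. Detection and storage still happen on
  $I_0$ itself.
* **Masked far boundary.** During rate calculations the far z-boundary is
  reflective for the cargo, so the pore is the only route between
  compartments; otherwise the periodic boundary would let the direct-rate
  oracle count transport that bypassed the pore and the FFS/direct
  comparison would be meaningless.
* **Overdamped trials.** There is no velocity to redraw; trials branch
  from stored snapshots and differ only in their derived noise streams,
  every one of which is reproducible from the master seed.

The primary oracle for the whole FFS machinery is a potential-free toy
(pore without chains, point cargo), where the assembled $k_{AB}$ is
compared against a long direct simulation that counts A-to-B transitions
per unit A-time with identical basin definitions; the suite requires
agreement within three combined standard errors.

## The reduced test systems

Desk-scale work uses `generate_reduced_fixture()`: chain length, chain
count and pore height scale linearly with `scale`, transverse dimensions
(box, $D$) with `sqrt(scale)`. This preserves the regime the theory
assumes, $D < D^*$, which a uniform shrink would break: at `scale = 0.1`
the fixture has 8 chains of 21 beads in a 12 nm pore with
$D^* \approx 13.5$ nm. The fixture emulates the architecture of the full
system — anchored semi-dilute chains in a pore, periodic stickers, the
same force field — but not its scale separation: chains are short (the
stiffness crossover is visible in their statistics), pores are a few mesh
sizes wide, and wall effects reach a larger fraction of the pore volume.
Passing tests on the fixture therefore validate the machinery and the
qualitative physics (rates rise with $D$, fall with $d$, and linearize in
the model's $u$ variable), not the quantitative $\gamma$ of the full-scale
system, which requires the cluster-scale sweep ($N = 209$,
$D = 40\!-\!60$ nm, $d = 1\!-\!6$ nm) to reproduce.

Problem sizes used by the test suite, chosen to keep each statistical
check's estimator error well inside its asserted tolerance: diffusion
checks use 200 free walkers or a single cargo over $10^4$–$3\times10^5$
steps with time-averaged mean-square displacements; bond-lifetime samples
collect 600 unbinding events; the FFS-vs-direct comparison runs a few
$10^7$ toy steps; the transport-rate sweep uses 8 chains of 21 beads in a
6 nm-high pore on a widely spaced grid of two pore diameters
($D/D^* \approx 0.78$ and $0.96$) and two cargo sizes (1 and 1.5 nm),
with 40 entry crossings and 500–1000 trials per condition, so every
monotone comparison spans a rate step several times larger than the
cells' sampling noise. One caveat on reproducibility: trajectories are
bit-reproducible for a given compiled engine, but chaotic dynamics amplify
floating-point differences between compiler builds, so sampled rates are
identical across runs of one installation rather than across machines or
compilers.

## Numerical behaviour and known limitations

* **Stability margin of the standard parameter set.** With $k_b = 100$,
  $\zeta = 3\pi\eta \approx 350$ and $\Delta t = 1$, the stiffest
  collective bond modes of long chains sit at the Euler stability edge
  ($4\cdot 2k_b/\zeta \approx 2.3 > 2$); the nonlinearity of the bond
  potential saturates them into slightly "hot" bonds (mean bond energy
  above $k_BT/2$, equilibrium bond length a few percent above $r_{eq}$).
  This is a property of the stated model (fixed $\Delta t$, stiff springs),
  reproduced faithfully rather than regularized away. Controls that need
  exact reference statistics (the ideal-chain scaling check, the
  bond-length Boltzmann test) therefore run at elevated friction, which
  refines the effective time step relative to the stiff modes without
  changing the equilibrium being sampled.
* **Chain-length crossover.** At desk-scale chain lengths the bending
  term ($k_a = 0.5$) gives a Kuhn segment of several beads, so apparent
  Flory exponents from short self-avoiding chains exceed the asymptotic
  good-solvent value; the suite asserts the good-solvent inequality
  $\hat\nu > 1/2$ and checks the exact ideal-chain control, leaving the
  asymptotic $\nu \approx 0.588$ to full-scale chains.
* **Mesh estimator.** The in-pore correlation length is estimated as the
  mean nearest-neighbour distance between beads of different chains in a
  core region (radius $D/2 - \sigma$, central 80% of the height) with a
  bootstrap standard error over snapshots. It matches constructed
  configurations and the Poisson-gas closed form, and is deliberately
  swappable: any estimator consistent with "typical distance between
  distinct chains" may be substituted.
* **Degenerate inputs.** Bound pairs at zero separation skip that step's
  pair force (counted and reported); zero-length bonds and degenerate
  angle triplets abort with a diagnostic; non-finite forces abort rather
  than propagate.
* **Determinism.** All randomness flows from one master seed through
  hash-derived streams (`derive_stream()`); runs, FFS phases and
  checkpoint-resumed trajectories are bit-reproducible, and every
  checkpoint carries the complete state including the generator.

## Fitting the model to simulated rates

The end-to-end workflow on the reduced scale:

```{r workflow, eval = FALSE}
cfg <- npc_config(box = c(20, 20, 18), h = 6, D = 10.6, N = 21, n_FG = 8,
                  n_ffs = 8, equil_steps = 2e5)
sys <- build_system(cfg, seed = 20)
sys <- run_bd(sys, cfg$equil_steps)
sys <- attach_cargo(sys, d = 1.5)
ffs <- run_ffs(sys, seed = 40, partial_only = TRUE)
ffs$k_AB_partial   # partial transport rate, ns^-1
```

Collect `k_AB_partial` over a $(D, d)$ grid into a data frame with columns
`D`, `d`, `rate`, then

```{r fit, eval = FALSE}
sc  <- reference_scales(polymer_params(N = 21, n_FG = 8, h = 6))
fit <- fit_gamma_k0(rates, sc)
glance(fit)       # gamma, k0, R^2
autoplot(fit)     # data and fitted exponential on the u axis
```

The same calls operate unchanged on full-scale sweeps.
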