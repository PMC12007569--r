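# Synthetic rocker-switch ensemble generator.
#
# Emulates the data regime of the pyruvate-carrier modelling study: a
# two-protomer transporter whose H2-H3 helix bundles rotate rigidly between
# an outward-open (t = 0) and an inward-open (t = 1) endpoint, closing the
# N-terminal gate and opening the C-terminal gate on the way. Models are
# backbone-only (N, CA, C, O): the gate coordination metric only sees
# non-hydrogen atoms, and a backbone-only template keeps the generator
# transparent and fast.
#
# Geometry (z = membrane normal). Each chain has a static vertical helix H1
# and a mobile H2-H3 bundle that rotates about a horizontal axis (along y)
# through the chain's pivot point. The gate-bearing helices H2 (N-gate) and
# H3 (C-gate) lie horizontally along y, above and below the pivot, so the
# whole gate segment of one chain keeps a single lever arm and the two
# chains' gate rods approach each other edge-on, reaching x-registry exactly
# at the gate's closed endpoint (t = 1 for the N-gate, t = 0 for the
# C-gate). A small vertical stagger between the paired rods sets the
# contact distance at registry. This makes both gate coordination numbers
# strictly monotone and roughly linear in the progress coordinate t, the
# regime in which filtering, clustering and state classification are
# exercised. The layout is an idealized abstraction of a rocker-switch
# gate, not a model of the real fold (see the methods vignette).

# ---- template layout constants (Angstrom / degrees) ----
SYN_RISE <- 1.5       # helix rise per residue
SYN_LEVER_N <- 12.0   # pivot -> N-gate rod lever arm (z)
SYN_LEVER_C <- 12.0   # pivot -> C-gate rod lever arm (z)
SYN_STAGGER_N <- 2.2  # vertical offset between the paired N-gate rods
SYN_STAGGER_C <- 2.2  # vertical offset between the paired C-gate rods
SYN_H1_X <- 12.0      # |x| of the static H1 helices

# combined x-travel of a gate (both chains) for rotations theta_a/theta_b,
# used to place the rods so x-registry falls exactly at the closed endpoint
syn_travel <- function(lever, theta_a, theta_b) {
  lever * (sin(theta_a / 2 * pi / 180) + sin(theta_b / 2 * pi / 180))
}

# idealized alpha-helix backbone atom placement: cylindrical offsets
# (radius, phase offset deg, axial offset) per atom relative to the CA wave
SYN_BB <- list(
  N  = c(1.58, -27.5, -0.98),
  CA = c(2.27,   0.0,  0.00),
  C  = c(1.70,  23.5,  1.05),
  O  = c(2.00,  21.0,  2.28)
)

# Straight helix backbone along +z ("z") or +y ("y").
# spec: res (numbers), center (xyz of the axial midpoint), axis, phase.
helix_atoms <- function(chain, spec) {
  res <- spec$res
  mid <- (min(res) + max(res)) / 2
  rows <- vector("list", length(res))
  for (i in seq_along(res)) {
    ax <- (res[i] - mid) * SYN_RISE
    phi0 <- spec$phase + (res[i] - min(res)) * 100
    at <- t(vapply(SYN_BB, function(p) {
      phi <- (phi0 + p[2L]) * pi / 180
      a <- ax + p[3L]
      r <- p[1L]
      if (spec$axis == "z") {
        c(spec$center[1L] + r * cos(phi), spec$center[2L] + r * sin(phi),
          spec$center[3L] + a)
      } else {
        c(spec$center[1L] + r * cos(phi), spec$center[2L] + a,
          spec$center[3L] + r * sin(phi))
      }
    }, numeric(3L)))
    rows[[i]] <- data.frame(
      chain_id = chain, res_seq = res[i], res_name = "GLY",
      atom_name = names(SYN_BB), element = c("N", "C", "C", "O"),
      x = at[, 1L], y = at[, 2L], z = at[, 3L], het = FALSE,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# chain layouts in the mid-transition frame; `side` is -1 for chain A
# (x < 0) and +1 for chain B. Residue numbering is chosen so the
# pyruvate-carrier gate groups (MPC1L chain A, MPC2 chain B) select real
# residues: N-gate on H2, C-gate on H3.
syn_chain_layout <- function(theta_a, theta_b) {
  half_n <- syn_travel(SYN_LEVER_N, theta_a, theta_b) / 2
  half_c <- syn_travel(SYN_LEVER_C, theta_a, theta_b) / 2
  mk <- function(chain, side, theta, h1_res, h2_res, h3_res, phase0) {
    list(
      chain = chain, side = side, theta = theta,
      # pivot of the mobile bundle (rotation axis runs along y through it)
      pivot = c(side * 2.0, 0, 0),
      h1 = list(res = h1_res, axis = "z",
                center = c(side * SYN_H1_X, 0, 0), phase = phase0),
      # N-gate rod: above the pivot; rods reach x-registry at t = 1
      h2 = list(res = h2_res, axis = "y",
                center = c(side * half_n, 0,
                           SYN_LEVER_N - side * SYN_STAGGER_N / 2),
                phase = phase0 + 40),
      # C-gate rod: below the pivot; rods start at x-registry at t = 0
      h3 = list(res = h3_res, axis = "y",
                center = c(side * half_c, 0,
                           -SYN_LEVER_C + side * SYN_STAGGER_C / 2),
                phase = phase0 + 80)
    )
  }
  list(
    A = mk("A", -1, theta_a, h1_res = 20:40, h2_res = 65:85, h3_res = 44:58,
           phase0 = 0),
    B = mk("B", +1, theta_b, h1_res = 30:50, h2_res = 79:99, h3_res = 58:72,
           phase0 = 25)
  )
}

# rotate rows of xyz by angle_deg about the axis through `origin` along
# unit vector `dir`
rotate_about_axis <- function(xyz, origin, dir, angle_deg) {
  u <- dir / sqrt(sum(dir^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3L, 3L,
              byrow = TRUE)
  R <- diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  centered <- sweep(xyz, 2L, origin)
  sweep(centered %*% t(R), 2L, origin, `+`)
}

syn_bundle_residues <- function(ch) c(ch$h2$res, ch$h3$res)

#' Build the synthetic transporter template (outward-open endpoint)
#'
#' Deterministic idealized heterodimer: chains A and B, three straight
#' helical backbones each, arranged around a pseudo-twofold axis along the
#' membrane normal. The default pyruvate-carrier gate groups
#' ([mpc_gate_metrics()], MPC1L numbering on chain A and MPC2 numbering on
#' chain B) select real, disjoint residue sets: the N-gate groups sit on the
#' mobile H2 helices, the C-gate groups on the mobile H3 helices. The
#' template is the `t = 0` (outward-open: N-gate open, C-gate closed)
#' endpoint; rotating the H2-H3 bundles by the full `theta` angles about
#' their pivot axes produces the inward-open endpoint.
#'
#' @param theta_a,theta_b Full bundle rotation (degrees) of chains A and B
#'   between the endpoints (defaults 16.5 and 19, the transporter's two
#'   protomer rotations).
#' @return A `StructureModel`; `meta` records the generator ground truth:
#'   pivot points, rotation senses, bundle and fixed residue sets, and the
#'   `hinge_onset` residues where mobile numbering begins.
#' @export
build_template <- function(theta_a = 16.5, theta_b = 19.0) {
  check_that(theta_a > 0 && theta_a < 90 && theta_b > 0 && theta_b < 90,
             "theta angles must be in (0, 90) degrees")
  layout <- syn_chain_layout(theta_a, theta_b)
  atoms <- do.call(rbind, lapply(layout, function(ch) {
    rbind(helix_atoms(ch$chain, ch$h1),
          helix_atoms(ch$chain, ch$h3),
          helix_atoms(ch$chain, ch$h2))
  }))
  rownames(atoms) <- NULL
  # helices are laid out in the mid-transition frame; tilt each bundle back
  # by half its angle to obtain the outward-open endpoint. Chain A closes
  # with a + rotation about +y, chain B (mirrored in x) with a - rotation.
  senses <- c(A = +1, B = -1)
  theta <- c(A = theta_a, B = theta_b)
  for (ch in layout) {
    rows <- atoms$chain_id == ch$chain &
      atoms$res_seq %in% syn_bundle_residues(ch)
    atoms[rows, c("x", "y", "z")] <- rotate_about_axis(
      as.matrix(atoms[rows, c("x", "y", "z")]),
      ch$pivot, c(0, 1, 0), -senses[[ch$chain]] * theta[[ch$chain]] / 2
    )
  }
  structure_model(
    "synthetic_template#1", atoms,
    meta = list(
      theta = theta,
      senses = senses,
      pivots = list(A = layout$A$pivot, B = layout$B$pivot),
      bundle_residues = list(A = syn_bundle_residues(layout$A),
                             B = syn_bundle_residues(layout$B)),
      fixed_residues = list(A = layout$A$h1$res, B = layout$B$h1$res),
      hinge_onset = c(A = min(syn_bundle_residues(layout$A)),
                      B = min(syn_bundle_residues(layout$B)))
    )
  )
}

# apply progress t to a template: rotate both bundles by t * theta about
# their pivot axes
syn_apply_progress <- function(template, t) {
  atoms <- template$atoms
  meta <- template$meta
  for (chain in c("A", "B")) {
    rows <- atoms$chain_id == chain &
      atoms$res_seq %in% meta$bundle_residues[[chain]]
    atoms[rows, c("x", "y", "z")] <- rotate_about_axis(
      as.matrix(atoms[rows, c("x", "y", "z")]),
      meta$pivots[[chain]], c(0, 1, 0),
      meta$senses[[chain]] * t * meta$theta[[chain]]
    )
  }
  atoms
}

draw_progress <- function(n, t_distribution, beta_shape) {
  switch(t_distribution,
    uniform = stats::runif(n),
    beta = stats::rbeta(n, beta_shape[1L], beta_shape[2L]),
    two_modes = {
      m <- stats::rbinom(n, 1L, 0.5)
      stats::rbeta(n, 2, 8) * (1 - m) + stats::rbeta(n, 8, 2) * m
    },
    linspace = if (n == 1L) 0.5 else seq(0, 1, length.out = n),
    stop(sprintf("unknown t_distribution '%s'", t_distribution), call. = FALSE)
  )
}

#' Generate a synthetic rocker-switch ensemble with ground truth
#'
#' Draws a progress coordinate `t` in `[0, 1]` per model (0 = outward-open,
#' 1 = inward-open), rotates each chain's H2-H3 bundle by `t * theta` about
#' its pivot axis, adds isotropic Gaussian coordinate noise, and attaches a
#' pseudo quality score per model. Fully reproducible: identical parameters
#' and seed give identical output.
#'
#' @param n_models Number of models.
#' @param t_distribution `"uniform"` (default), `"beta"`, `"two_modes"`, or
#'   `"linspace"` (deterministic evenly spaced t, for diagnostics).
#' @param beta_shape Length-2 shape for `t_distribution = "beta"`.
#' @param theta_a,theta_b Endpoint bundle rotations, degrees.
#' @param noise_sigma Isotropic Gaussian coordinate noise, Angstrom.
#' @param seed Integer seed; all randomness derives from it.
#' @param score_model `"unbiased"` (pseudo-score independent of t, so
#'   quality filtering is unbiased) or `"mid_biased"` (scores dip for
#'   mid-transition models, for probing filter/landscape interactions).
#' @return List with `models` (list of `StructureModel`), `truth`
#'   (`data.frame`: `model_id`, `t`, `angle_a`, `angle_b`, `pseudo_score`)
#'   and the `template`.
#' @export
generate_ensemble <- function(n_models = 2000, t_distribution = "uniform",
                              beta_shape = c(2, 2), theta_a = 16.5,
                              theta_b = 19.0, noise_sigma = 0.15, seed = 1,
                              score_model = c("unbiased", "mid_biased")) {
  check_that(n_models >= 1, "n_models must be >= 1")
  check_that(noise_sigma >= 0, "noise_sigma must be >= 0")
  score_model <- match.arg(score_model)
  template <- build_template(theta_a = theta_a, theta_b = theta_b)
  n_atoms <- nrow(template$atoms)
  tt <- NULL
  scores <- NULL
  models <- NULL
  with_seed(seed, {
    tt <- draw_progress(n_models, t_distribution, beta_shape)
    scores <- pmin(1, pmax(0, 1 - abs(stats::rnorm(n_models, 0, 0.15))))
    if (score_model == "mid_biased") {
      scores <- pmin(1, pmax(0, scores - 0.45 * exp(-(tt - 0.5)^2 / 0.02)))
    }
    models <- vector("list", n_models)
    for (i in seq_len(n_models)) {
      atoms <- syn_apply_progress(template, tt[i])
      if (noise_sigma > 0) {
        atoms[, c("x", "y", "z")] <- as.matrix(atoms[, c("x", "y", "z")]) +
          matrix(stats::rnorm(3L * n_atoms, 0, noise_sigma), n_atoms, 3L)
      }
      models[[i]] <- structure_model(
        sprintf("synthetic#%04d", i), atoms,
        meta = list(t = tt[i], pseudo_score = scores[i], seed = seed)
      )
    }
  })
  truth <- data.frame(
    model_id = vapply(models, function(m) m$model_id, character(1L)),
    t = tt,
    angle_a = tt * theta_a,
    angle_b = tt * theta_b,
    pseudo_score = scores,
    stringsAsFactors = FALSE
  )
  list(models = models, truth = truth, template = template)
}

#' Write a generated ensemble to disk
#'
#' Writes the multi-model PDB, the ground-truth TSV and a two-column
#' `model_id` / `score` TSV next to each other.
#'
#' @param ensemble Result of [generate_ensemble()].
#' @param prefix Output path prefix (files `<prefix>.pdb`,
#'   `<prefix>_truth.tsv`, `<prefix>_scores.tsv`).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_ensemble <- function(ensemble, prefix) {
  paths <- c(pdb = paste0(prefix, ".pdb"),
             truth = paste0(prefix, "_truth.tsv"),
             scores = paste0(prefix, "_scores.tsv"))
  write_models(ensemble$models, paths[["pdb"]])
  utils::write.table(ensemble$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(model_id = ensemble$truth$model_id,
               score = ensemble$truth$pseudo_score),
    paths[["scores"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(paths)
}
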