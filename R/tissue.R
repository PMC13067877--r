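#' Build a structured hexahedral cuboid mesh
#'
#' Uniform trilinear hexahedral discretization of an `lx x ly x lz` mm
#' cuboid with spacing `h`; fibers aligned with +z (the longitudinal axis).
#' The study geometry, `build_cuboid_mesh(1.8, 1.8, 18, 0.3)`, has
#' 6 x 6 x 60 = 2,160 elements and 7 x 7 x 61 = 2,989 nodes.
#'
#' @param lx,ly,lz Edge lengths (mm), each an integer multiple of `h`.
#' @param h Spacing (mm).
#' @return List of class `hex_mesh`: `nodes` (n x 3, mm), `elems`
#'   (ne x 8 node indices, 1-based), `h`, `dims`, `fiber` (unit vector),
#'   `nx`, `ny`, `nz` (element counts per axis).
#' @export
build_cuboid_mesh <- function(lx, ly, lz, h) {
  n_el <- c(lx, ly, lz) / h
  if (any(abs(n_el - round(n_el)) > 1e-9))
    stop("each dimension must be an integer multiple of h")
  n_el <- as.integer(round(n_el))
  nx <- n_el[1]; ny <- n_el[2]; nz <- n_el[3]
  xs <- seq(0, lx, by = h); ys <- seq(0, ly, by = h); zs <- seq(0, lz, by = h)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  idx <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  off <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
               c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  cells <- as.matrix(expand.grid(i = 0:(nx - 1), j = 0:(ny - 1),
                                 k = 0:(nz - 1)))
  elems <- matrix(0L, nrow(cells), 8)
  for (a in 1:8)
    elems[, a] <- idx(cells[, 1] + off[a, 1], cells[, 2] + off[a, 2],
                      cells[, 3] + off[a, 3])
  structure(list(nodes = nodes, elems = elems, h = h,
                 dims = c(lx, ly, lz), fiber = c(0, 0, 1),
                 nx = nx, ny = ny, nz = nz),
            class = "hex_mesh")
}

#' Transversely isotropic conductivity tensor
#'
#' `D = sigma_l * ((1 - r) n (x) n + r I)`: eigenvalue `sigma_l` along the
#' fiber direction `n`, `sigma_l * r` transverse (twice degenerate).
#'
#' @param n Unit fiber direction (length 3).
#' @param sigma_l Longitudinal conductivity (S/cm), default 0.0023.
#' @param r Transverse-to-longitudinal ratio, default 0.35 (0 < r <= 1).
#' @return Symmetric positive-definite 3 x 3 matrix.
#' @export
conductivity_tensor <- function(n, sigma_l = 0.0023, r = 0.35) {
  if (abs(sqrt(sum(n^2)) - 1) > 1e-8) stop("fiber direction must be a unit vector")
  if (!(r > 0 && r <= 1)) stop("need 0 < r <= 1")
  sigma_l * ((1 - r) * tcrossprod(n) + r * diag(3))
}

#' Monodomain solver configuration
#'
#' Tissue parameters and solver settings. The diffusion operator is the
#' conductivity tensor divided by `beta * cm` (surface-to-volume ratio
#' times membrane capacitance), which closes the units between S/cm,
#' uF/cm2 and ms; `beta = 1` recovers the raw reaction-diffusion form.
#' The default `beta` of 900 1/cm is in the ventricular range and is
#' calibrated so the default conductivities yield a physiological
#' longitudinal conduction velocity (about 49 cm/s on the reference mesh).
#'
#' @param sigma_l Longitudinal conductivity (S/cm).
#' @param r Anisotropy ratio sigma_t / sigma_l.
#' @param cm Membrane capacitance (uF/cm2).
#' @param beta Surface-to-volume ratio (1/cm).
#' @param dt Time step (ms).
#' @param cg_tol,cg_maxit Conjugate-gradient settings for the implicit
#'   (backward Euler) diffusion solve.
#' @return List of class `monodomain_config`.
#' @export
monodomain_config <- function(sigma_l = 0.0023, r = 0.35, cm = 1.0,
                              beta = 900, dt = 0.02, cg_tol = 1e-9,
                              cg_maxit = 200) {
  if (!(r > 0 && r <= 1)) stop("need 0 < r <= 1")
  if (dt <= 0) stop("dt must be positive")
  structure(list(sigma_l = sigma_l, r = r, cm = cm, beta = beta, dt = dt,
                 cg_tol = cg_tol, cg_maxit = cg_maxit),
            class = "monodomain_config")
}

# FEM operators on the structured mesh: stiffness matrix K (with the
# conductivity tensor folded in; trilinear shape functions, 2x2x2 Gauss)
# and the lumped mass vector M (row-sum lumping: h^3/8 per node per
# element). Mesh spacing is in mm; conductivities in S/cm, so lengths are
# converted to cm.
assemble_fem <- function(mesh, config) {
  h <- mesh$h / 10 # mm -> cm
  D <- conductivity_tensor(mesh$fiber, config$sigma_l, config$r)
  # reference-element geometry
  loc <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
               c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  gp <- 1 / sqrt(3)
  gauss <- as.matrix(expand.grid(x = c(-gp, gp), y = c(-gp, gp),
                                 z = c(-gp, gp)))
  detJ <- (h / 2)^3
  Ke <- matrix(0, 8, 8)
  for (g in seq_len(nrow(gauss))) {
    xi <- gauss[g, ]
    # global shape-function gradients (2/h factor from the Jacobian)
    B <- t(vapply(1:8, function(a) {
      la <- loc[a, ]
      (2 / h) * c(
        la[1] * (1 + la[2] * xi[2]) * (1 + la[3] * xi[3]),
        (1 + la[1] * xi[1]) * la[2] * (1 + la[3] * xi[3]),
        (1 + la[1] * xi[1]) * (1 + la[2] * xi[2]) * la[3]) / 8
    }, numeric(3)))
    Ke <- Ke + (B %*% D %*% t(B)) * detJ
  }
  ne <- nrow(mesh$elems); nn <- nrow(mesh$nodes)
  # triplets: for element e, entries (elems[e,a], elems[e,b]) = Ke[a,b]
  rows <- as.integer(mesh$elems[, rep(1:8, times = 8)])
  cols <- as.integer(mesh$elems[, rep(1:8, each = 8)])
  vals <- rep(as.numeric(Ke), each = ne)
  K <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(nn, nn))
  Mlump <- numeric(nn)
  contrib <- detJ # h^3/8 per node per element
  for (a in 1:8) {
    tab <- tabulate(mesh$elems[, a], nbins = nn)
    Mlump <- Mlump + tab * contrib
  }
  list(K = methods::as(K, "CsparseMatrix"), M = Mlump)
}

#' Nodes on a boundary face of the cuboid
#'
#' @param mesh `hex_mesh`.
#' @param face One of `"zmin"`, `"zmax"`, `"xmin"`, `"xmax"`, `"ymin"`,
#'   `"ymax"`.
#' @return Integer node indices.
#' @export
face_nodes <- function(mesh, face = "zmin") {
  z <- mesh$nodes[, 3]; x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
  tol <- 1e-9
  which(switch(face,
               zmin = z < min(z) + tol, zmax = z > max(z) - tol,
               xmin = x < min(x) + tol, xmax = x > max(x) - tol,
               ymin = y < min(y) + tol, ymax = y > max(y) - tol,
               stop("unknown face: ", face)))
}

#' Interior nodes for biomarker analysis
#'
#' Nodes away from the listed boundary faces (default: the paced and distal
#' z faces, where stimulus and boundary artifacts live).
#'
#' @param mesh `hex_mesh`.
#' @param exclude_faces Faces to exclude.
#' @return Integer node indices.
#' @export
analysis_nodes <- function(mesh, exclude_faces = c("zmin", "zmax")) {
  excl <- unique(unlist(lapply(exclude_faces, face_nodes, mesh = mesh)))
  setdiff(seq_len(nrow(mesh$nodes)), excl)
}

#' Assign population models to mesh nodes
#'
#' Random permutation (fixed seed) of the accepted models over the nodes,
#' recycling models if the population is smaller than the mesh.
#'
#' @param mesh `hex_mesh`.
#' @param acc Accepted population (from [accepted_models()]), or a scales
#'   matrix.
#' @param seed Permutation seed.
#' @return List: `scalings` (9 x n_nodes), `states` (41 x n_nodes or NULL),
#'   `model_of_node` (indices into the population).
#' @export
assign_models <- function(mesh, acc, seed = 1) {
  nn <- nrow(mesh$nodes)
  scales <- if (is.matrix(acc)) acc else acc$scales
  n_mod <- nrow(scales)
  if (n_mod < 1) stop("no models to assign")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sel <- sample(rep_len(sample(n_mod), nn))
  G <- matrix(1, length(SCALED_CURRENTS), nn,
              dimnames = list(SCALED_CURRENTS, NULL))
  G[colnames(scales), ] <- t(scales[sel, , drop = FALSE])
  S <- NULL
  if (!is.matrix(acc) && !is.null(acc$states) &&
      !any(vapply(acc$states, is.null, logical(1)))) {
    S <- vapply(acc$states[sel], as.numeric,
                numeric(length(ord_initial_state())))
  }
  list(scalings = G, states = S, model_of_node = sel)
}

#' Run a monodomain tissue simulation
#'
#' Operator-split monodomain on the hexahedral mesh: per-node ionic update
#' (the single-cell stepper) followed by an implicit backward-Euler
#' diffusion solve with zero-flux boundaries. The stimulus is applied to
#' the `stim_face` nodes (default the z = 0 end, so a planar wave
#' propagates along the fibers). Per-node initial states default to the
#' baseline single-cell limit cycle (pre-pacing strategy: pace cells in
#' isolation, embed, run few coupled beats).
#'
#' @param mesh `hex_mesh`.
#' @param protocol [pacing_protocol()]; `stim_amplitude = NULL` uses the
#'   tissue default of 100 uA/uF on the paced face.
#' @param config [monodomain_config()]; its `dt` overrides the protocol's.
#' @param scalings 9 x n_nodes matrix, a single [conductance_scaling()]
#'   recycled to all nodes, or NULL (baseline).
#' @param initial_states 41 x n_nodes matrix, a single state recycled, or
#'   NULL (baseline limit cycle).
#' @param drug,multiple Optional compound (name/record) applied at
#'   `multiple` x EFTPC to every node's scaling.
#' @param stim_face Face receiving the stimulus.
#' @param record_every Record every this many steps (default 12, ~0.25 ms).
#' @return List of class `tissue_trace`: `t`, `v` (time x nodes),
#'   `beat_start_idx`, `dt` (recording step), `bcl`, `n_beats`,
#'   `activation` (beats x nodes, ms within beat), `final_states`, `mesh`.
#' @export
run_monodomain <- function(mesh,
                           protocol = pacing_protocol(n_beats = 2,
                                                      n_recorded_beats = 2),
                           config = monodomain_config(),
                           scalings = NULL, initial_states = NULL,
                           drug = NULL, multiple = 1,
                           stim_face = "zmin", record_every = 12) {
  nn <- nrow(mesh$nodes)
  if (is.null(scalings)) scalings <- conductance_scaling()
  if (!is.matrix(scalings))
    scalings <- matrix(as_scaling(scalings), length(SCALED_CURRENTS), nn,
                       dimnames = list(SCALED_CURRENTS, NULL))
  if (!is.null(drug)) {
    rec <- as_drug_record(drug)
    for (i in seq_len(nn)) {
      g <- scalings[, i]
      names(g) <- SCALED_CURRENTS
      scalings[, i] <- apply_drug(g, rec, multiple)
    }
  }
  if (is.null(initial_states)) {
    st <- ord_limit_cycle_state(protocol = pacing_protocol(
      bcl = protocol$bcl, n_beats = 50, dt = config$dt,
      stim_duration = protocol$stim_duration))
    initial_states <- matrix(as.numeric(st), length(st), nn)
  } else if (!is.matrix(initial_states)) {
    initial_states <- matrix(as.numeric(initial_states),
                             length(ord_initial_state()), nn)
  }
  fem <- assemble_fem(mesh, config)
  Kc <- fem$K
  amp <- protocol$stim_amplitude %||% 100
  stim_nodes <- face_nodes(mesh, stim_face)
  diff_coef <- 1000 / (config$beta * config$cm) # unit closure S/cm..uF/cm2
  res <- monodomain_run_cpp(initial_states, scalings,
                            Kc@p, Kc@i, Kc@x, fem$M, diff_coef,
                            protocol$n_beats, protocol$bcl, config$dt,
                            amp, protocol$stim_duration,
                            as.integer(stim_nodes),
                            protocol$n_recorded_beats, record_every,
                            0, config$cg_tol, config$cg_maxit)
  structure(list(t = res$t, v = res$v, beat_start_idx = res$beat_start_idx,
                 dt = config$dt * record_every, bcl = protocol$bcl,
                 n_beats = length(res$beat_start_idx),
                 activation = res$activation,
                 final_states = res$final_states, mesh = mesh,
                 stim = list(amplitude = amp, duration =
                               protocol$stim_duration, face = stim_face),
                 config = config), class = "tissue_trace")
}

#' Extract one node's trace as an `ap_trace`
#'
#' @param tissue `tissue_trace`. @param node Node index.
#' @return `ap_trace` usable with [extract_features()] / [detect_events()].
#' @export
node_trace <- function(tissue, node) {
  structure(list(t = tissue$t, v = tissue$v[, node],
                 beat_start_idx = tissue$beat_start_idx,
                 dt = tissue$dt, bcl = tissue$bcl,
                 n_beats = tissue$n_beats,
                 stim = tissue$stim, scaling = NULL, final_state = NULL,
                 currents = NULL,
                 capture = {
                   w <- seq(tissue$beat_start_idx[tissue$n_beats],
                            length(tissue$t))
                   max(tissue$v[w, node]) > 0
                 }),
            class = "ap_trace")
}

#' Longitudinal conduction velocity from activation times
#'
#' Ordinary least squares of activation time against z over the interior
#' of the cuboid (default the central 25-75% of the fiber axis, away from
#' stimulus and boundary effects) on the chosen beat.
#'
#' @param tissue `tissue_trace`. @param beat Beat index (default last full
#'   activation).
#' @param z_range Fraction of the z extent used for the fit.
#' @return Conduction velocity in cm/s.
#' @export
conduction_velocity <- function(tissue, beat = NULL,
                                z_range = c(0.25, 0.75)) {
  act <- tissue$activation
  if (is.null(beat)) beat <- nrow(act)
  z <- tissue$mesh$nodes[, 3] # mm
  zr <- min(z) + z_range * (max(z) - min(z))
  sel <- which(z >= zr[1] & z <= zr[2] & !is.na(act[beat, ]))
  if (length(sel) < 10) stop("too few activated nodes for a CV fit")
  fit <- lm(act[beat, sel] ~ z[sel])
  slope <- coef(fit)[2] # ms per mm
  if (!is.finite(slope) || slope <= 0)
    stop("non-positive activation slope; no propagating wave")
  unname(100 / slope) # (1/slope) mm/ms = 100/slope cm/s
}

#' Estimated cardiomyocyte count of the tissue preparation
#'
#' Scales the human left-ventricular cardiomyocyte census (about 3.2e9
#' cells in 100-120 cm3) to a given tissue volume under uniform density,
#' rounded to one significant figure. The study cuboid
#' (0.18 x 0.18 x 1.8 cm = 0.05832 cm3) maps to about 2e6 cells.
#'
#' @param volume_cm3 Tissue volume (cm3); default the study cuboid.
#' @param total_cells LV cardiomyocyte count (default 3.2e9).
#' @param lv_volume_cm3 LV reference volume (default 110, the 100-120
#'   midpoint).
#' @return Estimated cell count (1 significant figure).
#' @export
estimate_cell_count <- function(volume_cm3 = 0.18 * 0.18 * 1.8,
                                total_cells = 3.2e9, lv_volume_cm3 = 110) {
  signif(total_cells / lv_volume_cm3 * volume_cm3, 1)
}

#' Export mesh and activation map
#'
#' Writes nodes and elements as CSV with a JSON header (dimensions,
#' spacing, fiber direction), and optionally an activation-time map.
#'
#' @param mesh `hex_mesh`. @param path Base path (writes
#'   `<path>_nodes.csv`, `<path>_elems.csv`, `<path>.json`).
#' @export
write_hex_mesh <- function(mesh, path) {
  write.csv(as.data.frame(mesh$nodes), paste0(path, "_nodes.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(mesh$elems), paste0(path, "_elems.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(dims = mesh$dims, h = mesh$h,
                            fiber = mesh$fiber),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hex_mesh
#' @param tissue `tissue_trace`. @param file Output CSV.
#' @export
write_activation_map <- function(tissue, file) {
  df <- cbind(as.data.frame(tissue$mesh$nodes),
              t(tissue$activation))
  names(df) <- c("x", "y", "z",
                 paste0("beat", seq_len(nrow(tissue$activation))))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
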