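#' Experiment configuration
#'
#' A declarative description of a full confinement experiment: one
#' structure (toy spec or PDB path), a list of cage sizes (nm, with `Inf`
#' meaning bulk), a temperature schedule, protocols and replica counts.
#' Every run's seed is derived from the master seed and the run index, so
#' a config reproduces its whole result bundle.
#'
#' @param structure either a [ca_structure()] or a PDB path.
#' @param cage_sizes numeric vector of cage half-sizes L in nm; `Inf` =
#'   bulk.
#' @param temperatures reduced temperatures for the equilibrium schedule.
#' @param n_steps steps per run.
#' @param n_replicas replicas per condition.
#' @param seed master seed.
#' @param record_stride frame recording stride.
#' @param knot_stride knot evaluation stride over frames (`NA` = skip).
#' @param out_dir output directory (`NULL` = in-memory only).
#' @param chain,contact_cutoff,min_sep structure/topology options.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(structure, cage_sizes = c(Inf, 2.5),
                              temperatures = c(115, 125), n_steps = 2e5,
                              n_replicas = 1L, seed = 1L,
                              record_stride = 1000L, knot_stride = NA,
                              out_dir = NULL, chain = "A",
                              contact_cutoff = 8.0, min_sep = 4L) {
  stopifnot(length(cage_sizes) >= 1, length(temperatures) >= 1)
  structure(list(structure = structure, cage_sizes = cage_sizes,
                 temperatures = temperatures, n_steps = n_steps,
                 n_replicas = as.integer(n_replicas), seed = as.numeric(seed),
                 record_stride = as.integer(record_stride),
                 knot_stride = knot_stride, out_dir = out_dir, chain = chain,
                 contact_cutoff = contact_cutoff, min_sep = as.integer(min_sep)),
            class = "experiment_config")
}

config_fingerprint <- function(cfg) {
  x <- cfg
  x$structure <- if (inherits(cfg$structure, "ca_structure")) {
    list(n = nrow(cfg$structure$coords),
         sum = round(sum(cfg$structure$coords), 6))
  } else as.character(cfg$structure)
  json <- jsonlite::toJSON(x[order(names(x))], auto_unbox = TRUE, digits = 10)
  tf <- tempfile()
  writeLines(json, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

#' Run a full experiment from a config
#'
#' For every condition (cage size x), runs the equilibrium temperature
#' schedule, combines it with WHAM into C_v(T), T_f and F(Q) at T_f,
#' computes observables (including knottedness when `knot_stride` is
#' set), the knotting profile P_K(Q), transition statistics at the
#' temperature closest to T_f, and per-contact formation profiles. When
#' `out_dir` is set, tables are written under one dated directory per
#' condition and a manifest records seeds, parameters and the config
#' hash.
#'
#' @param cfg [experiment_config()]
#' @param quiet suppress progress messages.
#' @return list of class `experiment_result`: per condition `trajectories`,
#'   `wham`, `Tf`, `fq`, `series`, `pk`, `transitions`, `contact_profile`;
#'   plus `manifest` (data.frame) and `config`.
#' @export
run_experiment <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  s <- if (inherits(cfg$structure, "ca_structure")) {
    cfg$structure
  } else {
    if (!file.exists(cfg$structure)) stop("structure file not found: ",
                                          cfg$structure)
    read_pdb(cfg$structure, chain = cfg$chain)
  }
  topo <- build_native_topology(s, cfg$contact_cutoff, cfg$min_sep)
  say <- function(...) if (!quiet) message(sprintf(...))

  conditions <- list()
  manifest <- list()
  cond_idx <- 0L
  for (L in cfg$cage_sizes) {
    cond_idx <- cond_idx + 1L
    cage <- if (is.finite(L)) cage_spec(L) else NULL
    ff <- forcefield(topo, cage = cage)
    x0 <- if (is.null(cage)) s$coords else fit_to_cage(s$coords, cage,
                                                       clearance = 1)
    lbl <- if (is.finite(L)) sprintf("L=%g", L) else "bulk"
    say("condition %s: %d temperatures x %d replicas", lbl,
        length(cfg$temperatures), cfg$n_replicas)
    trajs <- list()
    for (ti in seq_along(cfg$temperatures)) {
      for (r in seq_len(cfg$n_replicas)) {
        run_seed <- derive_seed(cfg$seed, cond_idx * 10000L + ti * 100L + r)
        scfg <- sim_config(cfg$temperatures[ti], n_steps = cfg$n_steps,
                           record_stride = cfg$record_stride, seed = run_seed)
        trajs[[length(trajs) + 1L]] <- integrate_langevin(x0, ff, scfg)
        manifest[[length(manifest) + 1L]] <- data.frame(
          condition = lbl, temperature = cfg$temperatures[ti], replica = r,
          seed = run_seed, n_steps = cfg$n_steps)
      }
    }
    hs <- histogram_set(trajs, topology = topo)
    wr <- tryCatch(wham_solve(hs), warning = function(w) {
      suppressWarnings(wham_solve(hs))
    })
    cv <- heat_capacity(wr)
    tf <- tryCatch(locate_tf(cv), error = function(e) NA_real_)
    fq <- tryCatch(free_energy_profile(wr, if (is.na(tf))
      stats::median(cfg$temperatures) else tf), error = function(e) NULL)
    series <- lapply(seq_along(trajs), function(i) {
      observable_series(trajs[[i]], topo, knot_stride = cfg$knot_stride,
                        seed = derive_seed(cfg$seed, 900000L + i))
    })
    pk <- tryCatch(pk_profile(series), error = function(e) NULL)
    near_tf <- which.min(abs(cfg$temperatures -
                               if (is.na(tf)) stats::median(cfg$temperatures) else tf))
    tf_runs <- which(vapply(trajs, function(tr)
      tr$config$temperature == cfg$temperatures[near_tf], logical(1)))
    trans <- detect_transitions(do.call(rbind, lapply(series[tf_runs],
                                                      as.data.frame)))
    cp <- contact_profile(trajs, topo, condition = lbl)
    conditions[[lbl]] <- list(L = L, trajectories = trajs, wham = wr,
                              Tf = tf, cv = cv, fq = fq, series = series,
                              pk = pk, transitions = trans,
                              contact_profile = cp)
  }
  manifest <- do.call(rbind, manifest)
  res <- structure(list(conditions = conditions, manifest = manifest,
                        config = cfg,
                        config_hash = config_fingerprint(cfg)),
                   class = "experiment_result")
  if (!is.null(cfg$out_dir)) write_experiment(res, cfg$out_dir)
  res
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment_result: %d conditions (%s), config %s\n",
              length(x$conditions), paste(names(x$conditions), collapse = ", "),
              x$config_hash))
  invisible(x)
}

write_experiment <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(res$config_hash, file.path(out_dir, "config_hash.txt"))
  for (lbl in names(res$conditions)) {
    cd <- res$conditions[[lbl]]
    d <- file.path(out_dir, gsub("[^A-Za-z0-9_.=-]", "_", lbl))
    dir.create(d, showWarnings = FALSE)
    utils::write.table(cd$cv, file.path(d, "cv.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (!is.null(cd$fq)) {
      utils::write.table(as.data.frame(cd$fq), file.path(d, "fq.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (!is.null(cd$pk)) {
      utils::write.table(as.data.frame(cd$pk), file.path(d, "pk.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    writeLines(sprintf("Tf\t%.6g", cd$Tf), file.path(d, "tf.tsv"))
  }
  invisible(out_dir)
}
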