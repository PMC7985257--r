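#' Configuration for the synthetic two-site community generator
#'
#' Defines a host-plant community whose members sample fungal partners from a
#' shared rank-abundance backbone. Per-host preference over fungi is built
#' from four effect-size knobs:
#'
#' * `lambda` (nestedness decay, >= 0): fungal preferences follow a geometric
#'   profile `exp(-lambda * rank)` over a shared fungal ranking — steeper
#'   profiles concentrate reads on the leading fungi and produce a nested
#'   incidence structure with decaying fungal marginals.
#' * `breadth` (>= 0): spread of host-specific steepness multipliers
#'   (`exp(breadth * (position - 1/2))` across hosts). Positive breadth makes
#'   narrow hosts sample prefixes of what broad hosts sample — deterministic
#'   nested rows. With `breadth = 0` and `gamma = 0` all hosts share one
#'   generalist preference vector.
#' * `gamma` (specialization, >= 0): each host mixes in mass
#'   `gamma / (1 + gamma)` on a host-private specialist fungus set (fungi
#'   assigned round-robin across hosts), raising d', H2' and between-host
#'   dissimilarity while lowering nestedness.
#' * `epsilon` (noise, `[0, 1]`): contamination of each host's preference
#'   ranking by uniform-random rank scores. The geometric profile shape (and
#'   hence fill) is preserved while the cross-host rank alignment — the
#'   source of nestedness — degrades; at `epsilon = 1` host rankings are
#'   independent.
#'
#' @param n_hosts,n_fungi community dimensions.
#' @param plots_per_host replicate plots (samples) per host and site.
#' @param reads_per_sample sequencing depth of every sample.
#' @param lambda,gamma,epsilon,breadth effect-size knobs, see above.
#' @param seed integer RNG seed; identical configurations with identical
#'   seeds reproduce byte-identical outputs.
#' @return validated list of class `synthetic_config`.
#' @seealso [rural_config], [urban_config] for the two-site presets.
#' @export
synthetic_config <- function(n_hosts = 8, n_fungi = 81, plots_per_host = 5,
                             reads_per_sample = 4227, lambda = 12,
                             gamma = 0.5, epsilon = 0.05, breadth = 1,
                             seed = 1L) {
  stopifnot(n_hosts >= 2, n_fungi >= 2, plots_per_host >= 1,
            reads_per_sample >= 1, lambda >= 0, gamma >= 0, breadth >= 0,
            epsilon >= 0, epsilon <= 1)
  structure(list(n_hosts = as.integer(n_hosts), n_fungi = as.integer(n_fungi),
                 plots_per_host = as.integer(plots_per_host),
                 reads_per_sample = as.integer(reads_per_sample),
                 lambda = lambda, gamma = gamma, epsilon = epsilon,
                 breadth = breadth, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Rural-like generator preset
#'
#' Specialist-enriched, strongly nested regime: steep shared backbone
#' (`lambda = 20`), pronounced host-private specialist mass (`gamma = 1`),
#' host-breadth heterogeneity (`breadth = 1`), mild ranking noise.
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [synthetic_config].
#' @export
rural_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(lambda = 20, gamma = 1, epsilon = 0.05,
                                 breadth = 1, seed = seed), list(...))
  do.call(synthetic_config, args)
}

#' Urban-like generator preset
#'
#' Generalist-enriched, convergent regime: moderate backbone decay
#' (`lambda = 10`), little host-private mass (`gamma = 0.1`), near-uniform
#' host breadths (`breadth = 0.25`), mild ranking noise. Host communities are
#' similar (low Bray-Curtis) and the incidence structure is dense but not
#' significantly nested.
#'
#' @inheritParams rural_config
#' @export
urban_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(lambda = 10, gamma = 0.1, epsilon = 0.05,
                                 breadth = 0.25, seed = seed), list(...))
  do.call(synthetic_config, args)
}

# Per-host preference matrix (hosts x fungi, rows sum to 1) plus the pieces
# of ground truth used by recovery tests. Consumes RNG (ranking noise).
host_preferences <- function(cfg) {
  m <- cfg$n_hosts; n <- cfg$n_fungi
  global_rank <- (seq_len(n) - 0.5) / n
  steep <- if (m > 1)
    exp(cfg$breadth * ((seq_len(m) - 1) / (m - 1) - 0.5)) else 1
  mix <- cfg$gamma / (1 + cfg$gamma)
  pref <- matrix(0, m, n)
  for (h in seq_len(m)) {
    score <- (1 - cfg$epsilon) * global_rank + cfg$epsilon * stats::runif(n)
    profile <- exp(-cfg$lambda * steep[h] * (seq_len(n) - 1) / (n - 1))
    backbone <- numeric(n)
    backbone[order(score)] <- profile / sum(profile)
    private <- numeric(n)
    idx <- which(((seq_len(n) - 1) %% m) == (h - 1))
    pr <- exp(-5 * (seq_along(idx) - 1) / max(1, length(idx) - 1))
    private[idx] <- pr / sum(pr)
    pref[h, ] <- (1 - mix) * backbone + mix * private
  }
  if (any(rowSums(pref) <= 0)) stop("degenerate config: all-zero preferences",
                                    call. = FALSE)
  pref <- pref / rowSums(pref)
  dimnames(pref) <- list(host_labels(m), otu_labels(n))
  pref
}

host_labels <- function(m) sprintf("host%02d", seq_len(m))
otu_labels <- function(n) sprintf("OTU%03d", seq_len(n))

#' Generate one synthetic host-fungus interaction matrix
#'
#' Draws each host's aggregate weights multinomially
#' (`plots_per_host * reads_per_sample` reads over the host's preference
#' vector) and drops fungi that were never observed. Ground truth (the knob
#' values and the preference matrix) is attached as attribute `truth` for
#' parameter-recovery tests.
#'
#' @param cfg a [synthetic_config].
#' @return an [interaction_matrix] with attribute `truth`.
#' @export
generate_interaction_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    pref <- host_preferences(cfg)
    reads <- cfg$plots_per_host * cfg$reads_per_sample
    w <- t(apply(pref, 1, function(p)
      rowSums(stats::rmultinom(cfg$plots_per_host, cfg$reads_per_sample, p))))
    dimnames(w) <- dimnames(pref)
    w <- w[, colSums(w) > 0, drop = FALSE]
    im <- interaction_matrix(w)
    attr(im, "truth") <- list(config = unclass(cfg),
                              preferences = pref, reads_per_host = reads)
    im
  })
}

#' Generate a two-site (rural-like / urban-like) study
#'
#' Produces per-sample OTU tables for both site regimes — `plots_per_host`
#' samples per host per site, each of exactly `reads_per_sample` reads drawn
#' multinomially from the host's site-specific preference vector — sharing
#' one fungal OTU pool, plus the combined table the pipeline consumes.
#'
#' @param cfg_rural,cfg_urban [synthetic_config]s for the two regimes
#'   (defaults: [rural_config], [urban_config]). Community dimensions must
#'   agree.
#' @return object of class `two_site_study`: list with `combined`, `rural`,
#'   `urban` ([otu_table]s) and `truth` (per-site knob values and preference
#'   matrices).
#' @export
generate_two_site_study <- function(cfg_rural = rural_config(),
                                    cfg_urban = urban_config()) {
  stopifnot(inherits(cfg_rural, "synthetic_config"),
            inherits(cfg_urban, "synthetic_config"))
  if (cfg_rural$n_fungi != cfg_urban$n_fungi ||
      cfg_rural$n_hosts != cfg_urban$n_hosts)
    stop("the two site configs must share community dimensions", call. = FALSE)
  sites <- list(rural = cfg_rural, urban = cfg_urban)
  tabs <- list()
  truth <- list()
  for (s in names(sites)) {
    cfg <- sites[[s]]
    res <- with_seed(child_seed(cfg$seed, match(s, names(sites))), {
      pref <- host_preferences(cfg)
      hosts <- rownames(pref)
      counts <- matrix(0, cfg$n_hosts * cfg$plots_per_host, cfg$n_fungi,
                       dimnames = list(NULL, colnames(pref)))
      meta <- data.frame(sample = character(nrow(counts)), host = "",
                         site = s, plot = "", stringsAsFactors = FALSE)
      k <- 0
      for (h in seq_along(hosts)) for (p in seq_len(cfg$plots_per_host)) {
        k <- k + 1
        counts[k, ] <- stats::rmultinom(1, cfg$reads_per_sample, pref[h, ])
        meta$sample[k] <- sprintf("%s_%s_p%d", substr(s, 1, 3), hosts[h], p)
        meta$host[k] <- hosts[h]
        meta$plot[k] <- sprintf("p%d", p)
      }
      rownames(counts) <- meta$sample
      list(table = otu_table(counts, meta), pref = pref)
    })
    tabs[[s]] <- res$table
    truth[[s]] <- list(config = unclass(cfg), preferences = res$pref)
  }
  combined <- otu_table(rbind(tabs$rural$counts, tabs$urban$counts),
                        rbind(tabs$rural$metadata, tabs$urban$metadata))
  structure(list(combined = combined, rural = tabs$rural, urban = tabs$urban,
                 truth = truth), class = "two_site_study")
}

#' @export
print.two_site_study <- function(x, ...) {
  cat("two_site_study\n  rural: ")
  print(x$rural)
  cat("  urban: ")
  print(x$urban)
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits the combined counts and metadata TSVs in the dialect
#' [read_otu_table] consumes, plus a sidecar ground-truth JSON with the knob
#' values per site.
#'
#' @param study a `two_site_study`.
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_two_site_study <- function(study, dir) {
  stopifnot(inherits(study, "two_site_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts_path <- file.path(dir, "counts.tsv")
  meta_path <- file.path(dir, "metadata.tsv")
  truth_path <- file.path(dir, "truth.json")
  write_otu_table(study$combined, counts_path, meta_path)
  truth <- lapply(study$truth, function(t) t$config)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(counts = counts_path, metadata = meta_path, truth = truth_path))
}
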