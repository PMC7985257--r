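#' Analysis configuration for the two-site network pipeline
#'
#' Collects every tunable of the end-to-end analysis: preprocessing
#' thresholds, the rarefaction depth, null-model replicate counts, the
#' max-NODF search budget and the link-significance thresholds. One global
#' `seed` fans out to stage-specific child seeds (rarefaction, each null
#' ensemble, the optimizer), so stages are independently reproducible.
#'
#' @param counts_path,metadata_path optional input TSV paths (unused when an
#'   [otu_table] is supplied directly).
#' @param rare_otu_fraction rare-OTU threshold as a proportion of the grand
#'   read total (default `1e-6`, i.e. 0.0001%).
#' @param min_reads minimum per-sample depth retained before rarefaction.
#' @param rarefaction_depth common depth samples are rarefied to.
#' @param nodf_reps,nodfc_reps,swap_reps null-model replicate counts for the
#'   NODF EE/FF tests, the NODFc EE test, and the swap-web link/d' tests.
#' @param optimizer_restarts,optimizer_moves max-NODF search budget.
#' @param z_alpha,z_strong link/d' significance thresholds on `|z|` (strict
#'   inequalities).
#' @param log_base logarithm base in NODFc.
#' @param seed global RNG seed.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(counts_path = NULL, metadata_path = NULL,
                            rare_otu_fraction = 1e-6, min_reads = 4227,
                            rarefaction_depth = 4227,
                            nodf_reps = 999, nodfc_reps = 99, swap_reps = 999,
                            optimizer_restarts = 4, optimizer_moves = 2000,
                            z_alpha = 1.96, z_strong = 2.576,
                            log_base = exp(1), seed = 1L) {
  stopifnot(rare_otu_fraction >= 0, rare_otu_fraction < 1, min_reads >= 1,
            rarefaction_depth >= 1, nodf_reps >= 1, nodfc_reps >= 1,
            swap_reps >= 1, z_alpha > 0, z_strong > 0)
  structure(list(counts_path = counts_path, metadata_path = metadata_path,
                 rare_otu_fraction = rare_otu_fraction, min_reads = min_reads,
                 rarefaction_depth = rarefaction_depth,
                 nodf_reps = as.integer(nodf_reps),
                 nodfc_reps = as.integer(nodfc_reps),
                 swap_reps = as.integer(swap_reps),
                 optimizer_restarts = as.integer(optimizer_restarts),
                 optimizer_moves = as.integer(optimizer_moves),
                 z_alpha = z_alpha, z_strong = z_strong, log_base = log_base,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# Strip a null_ensemble down to its JSON-friendly summary.
ensemble_summary <- function(ne) {
  list(statistic = ne$statistic, scheme = ne$scheme, obs = ne$obs,
       mean = ne$mean, sd = ne$sd, z = ne$z, p_upper = ne$p_upper,
       p_lower = ne$p_lower, p_two_sided = ne$p_two_sided, reps = ne$reps)
}

#' Run the full analysis for one site
#'
#' Executes the pipeline filter -> exclude -> rarefy -> aggregate -> metrics
#' -> null tests for the samples of one site class, logging counts in/out at
#' every stage. Network metrics are computed on the site's host-by-OTU
#' matrix; NODF is tested against EE and FF nulls, NODFc against EE, and the
#' per-link weights and per-species d' against a shared swap-web ensemble.
#'
#' @param x an [otu_table] containing the site's samples (other sites are
#'   ignored).
#' @param site `"rural"` or `"urban"`.
#' @param cfg an [analysis_config].
#' @return list with the interaction matrix, the metric set (connectance,
#'   C-score, H2', NODF, NODFc), the null-ensemble summaries, per-species d'
#'   tables, the fungal degree distribution with significant-specialist
#'   counts, per-sample diversity, the host Bray-Curtis matrix, and a stage
#'   log.
#' @export
run_site_analysis <- function(x, site, cfg = analysis_config()) {
  stopifnot(inherits(x, "otu_table"), inherits(cfg, "analysis_config"))
  site <- match.arg(site, c("rural", "urban"))
  stage <- function(name, f) {
    tryCatch(f(), error = function(e)
      stop(sprintf("stage '%s' failed for site '%s': %s",
                   name, site, conditionMessage(e)), call. = FALSE))
  }
  log <- list()
  nw_log("run_site_analysis", sprintf("site %s: %d samples in", site,
                                      sum(x$metadata$site == site)))
  t1 <- stage("filter_rare_otus", function()
    filter_rare_otus(x, cfg$rare_otu_fraction))
  log$otus_removed <- length(attr(t1, "removed_otus"))
  t2 <- stage("exclude_low_depth_samples", function()
    exclude_low_depth_samples(t1, cfg$min_reads))
  log$samples_dropped <- length(attr(t2, "dropped_samples"))
  t3 <- stage("rarefy", function()
    rarefy_table(t2, cfg$rarefaction_depth, seed = child_seed(cfg$seed, 11)))
  im <- stage("aggregate_to_network", function() aggregate_to_network(t3, site))
  log$m <- nrow(im); log$n <- ncol(im); log$fill <- matrix_fill(im)
  nw_log("run_site_analysis", sprintf("site %s: %d hosts x %d OTUs, fill %d",
                                      site, nrow(im), ncol(im), matrix_fill(im)))

  site_offset <- if (site == "rural") 100L else 200L
  b <- binary_view(im)
  nodf_obs <- nodf(b)
  nodfc_obs <- nodfc(b, log_base = cfg$log_base,
                     restarts = cfg$optimizer_restarts,
                     moves = cfg$optimizer_moves,
                     seed = child_seed(cfg$seed, site_offset + 31))
  h2 <- h2_prime(im, seed = child_seed(cfg$seed, site_offset + 21))
  metrics <- list(m = nrow(im), n = ncol(im), fill = matrix_fill(im),
                  connectance = connectance(im),
                  cscore = c_score(b, margin = "fungi"),
                  h2prime = h2$H2prime,
                  h2_components = list(H2 = h2$H2, H2_min = h2$H2_min,
                                       H2_max = h2$H2_max),
                  nodf = nodf_obs$NODF,
                  nodfc = nodfc_obs$NODFc,
                  nodfc_components = list(NODF = nodfc_obs$NODF,
                                          max_NODF = nodfc_obs$max_NODF,
                                          C = nodfc_obs$C, S = nodfc_obs$S))

  nw_log("run_site_analysis", sprintf("site %s: null models", site))
  nodf_ee <- null_test(b, "nodf", "EE", reps = cfg$nodf_reps,
                       seed = child_seed(cfg$seed, site_offset + 41))
  nodf_ff <- null_test(b, "nodf", "FF", reps = cfg$nodf_reps,
                       seed = child_seed(cfg$seed, site_offset + 42))
  nodfc_ee <- null_test(b, "nodfc", "EE", reps = cfg$nodfc_reps,
                        seed = child_seed(cfg$seed, site_offset + 43),
                        restarts = cfg$optimizer_restarts,
                        moves = cfg$optimizer_moves)

  swap_seed <- child_seed(cfg$seed, site_offset + 44)
  links <- link_zscores(im, reps = cfg$swap_reps, seed = swap_seed,
                        z_alpha = cfg$z_alpha, z_strong = cfg$z_strong)
  dprime_fungi <- dprime_zscores(im, margin = "fungi", reps = cfg$swap_reps,
                                 seed = swap_seed, z_alpha = cfg$z_alpha,
                                 z_strong = cfg$z_strong)
  dprime_hosts <- dprime_zscores(im, margin = "hosts", reps = cfg$swap_reps,
                                 seed = swap_seed, z_alpha = cfg$z_alpha,
                                 z_strong = cfg$z_strong)

  deg <- degree_distribution(im, margin = "fungi")
  deg$significant_specialists <- vapply(deg$degree, function(d)
    sum(dprime_fungi$degree == d & dprime_fungi$significant), integer(1))

  diversity <- sample_diversity(subset_site(t3, site))
  host_bc <- host_dissimilarity(im)

  list(site = site, interaction_matrix = im, metrics = metrics,
       nulls = list(nodf_ee = ensemble_summary(nodf_ee),
                    nodf_ff = ensemble_summary(nodf_ff),
                    nodfc_ee = ensemble_summary(nodfc_ee)),
       dprime_hosts = dprime_hosts, dprime_fungi = dprime_fungi,
       degree_distribution = deg, link_z = links$z,
       link_significant = links$significant,
       diversity = diversity, host_bc = host_bc, stage_log = log)
}

subset_site <- function(x, site) {
  keep <- x$metadata$site == site
  otu_table(x$counts[keep, , drop = FALSE],
            x$metadata[keep, , drop = FALSE])
}

#' Compare the rural and urban networks
#'
#' Runs [run_site_analysis] on both site classes and assembles the
#' side-by-side report: per-site descriptive statistics and null tests, plus
#' the cross-site host-dissimilarity comparison (paired t test on the
#' host-pair Bray-Curtis values, pairs matched across sites). No
#' multiple-testing correction is applied to the per-link tests; the report
#' carries that as an explicit note.
#'
#' @param x an [otu_table] with samples from both sites.
#' @param cfg an [analysis_config].
#' @return object of class `network_report`.
#' @export
compare_sites <- function(x, cfg = analysis_config()) {
  sites <- list(rural = run_site_analysis(x, "rural", cfg),
                urban = run_site_analysis(x, "urban", cfg))
  shared <- intersect(rownames(sites$rural$host_bc),
                      rownames(sites$urban$host_bc))
  comparison <- list()
  if (length(shared) >= 3) {
    br <- sites$rural$host_bc[shared, shared]
    bu <- sites$urban$host_bc[shared, shared]
    tt <- paired_t_test(pairwise_values(br), pairwise_values(bu))
    comparison$bc_paired_t <- c(tt, list(
      n_pairs = length(pairwise_values(br)),
      mean_rural = mean(pairwise_values(br)),
      mean_urban = mean(pairwise_values(bu))))
  }
  comparison$nodf_diff <- sites$rural$metrics$nodf - sites$urban$metrics$nodf
  comparison$nodfc_diff <- sites$rural$metrics$nodfc - sites$urban$metrics$nodfc
  comparison$mean_dprime_hosts <- list(
    rural = mean(sites$rural$dprime_hosts$dprime),
    urban = mean(sites$urban$dprime_hosts$dprime))
  report <- list(sites = sites, comparison = comparison,
                 notes = paste("Per-link z tests are uncorrected for multiple",
                               "comparisons; interpret link-level flags",
                               "accordingly."),
                 provenance = list(seed = cfg$seed,
                                   config = unclass(cfg),
                                   package_version =
                                     as.character(utils::packageVersion("nestweb")),
                                   generated = "nestweb::compare_sites"))
  class(report) <- "network_report"
  report
}

#' @export
print.network_report <- function(x, ...) {
  cat("Two-site plant-fungal network report\n")
  cat(sprintf("%-22s %10s %10s\n", "", "rural", "urban"))
  row <- function(label, fr, fu, fmt = "%10.4f")
    cat(sprintf("%-22s %s %s\n", label, sprintf(fmt, fr), sprintf(fmt, fu)))
  s <- x$sites
  cat(sprintf("%-22s %10s %10s\n", "hosts x OTUs",
              sprintf("%dx%d", s$rural$metrics$m, s$rural$metrics$n),
              sprintf("%dx%d", s$urban$metrics$m, s$urban$metrics$n)))
  row("connectance", s$rural$metrics$connectance, s$urban$metrics$connectance)
  row("C-score", s$rural$metrics$cscore, s$urban$metrics$cscore)
  row("H2'", s$rural$metrics$h2prime, s$urban$metrics$h2prime)
  row("NODF", s$rural$metrics$nodf, s$urban$metrics$nodf, "%10.2f")
  row("  null mean (EE)", s$rural$nulls$nodf_ee$mean, s$urban$nulls$nodf_ee$mean, "%10.2f")
  row("  P (EE, upper)", s$rural$nulls$nodf_ee$p_upper, s$urban$nulls$nodf_ee$p_upper)
  row("  null mean (FF)", s$rural$nulls$nodf_ff$mean, s$urban$nulls$nodf_ff$mean, "%10.2f")
  row("  P (FF, upper)", s$rural$nulls$nodf_ff$p_upper, s$urban$nulls$nodf_ff$p_upper)
  row("NODFc", s$rural$metrics$nodfc, s$urban$metrics$nodfc)
  row("  P (EE, upper)", s$rural$nulls$nodfc_ee$p_upper, s$urban$nulls$nodfc_ee$p_upper)
  row("mean host d'", x$comparison$mean_dprime_hosts$rural,
      x$comparison$mean_dprime_hosts$urban)
  if (!is.null(x$comparison$bc_paired_t))
    cat(sprintf("host Bray-Curtis: rural %.4f vs urban %.4f (paired t = %s, P = %.4g)\n",
                x$comparison$bc_paired_t$mean_rural,
                x$comparison$bc_paired_t$mean_urban,
                if (is_undefined(x$comparison$bc_paired_t$t)) "NA"
                else sprintf("%.3f", x$comparison$bc_paired_t$t),
                x$comparison$bc_paired_t$p))
  invisible(x)
}

# Convert report pieces (matrices, data.frames) to JSON-stable structures.
report_to_json_list <- function(report) {
  strip_site <- function(s) {
    s$interaction_matrix <- list(
      row_labels = rownames(s$interaction_matrix),
      col_labels = colnames(s$interaction_matrix),
      weights = unname(apply(unclass(s$interaction_matrix), 1, as.numeric,
                             simplify = FALSE)))
    s$host_bc <- list(labels = rownames(s$host_bc),
                      values = unname(apply(s$host_bc, 1, as.numeric,
                                            simplify = FALSE)))
    s$link_z <- unname(apply(s$link_z, 1, as.numeric, simplify = FALSE))
    s$link_significant <- unname(apply(s$link_significant, 1, as.logical,
                                       simplify = FALSE))
    s
  }
  list(sites = lapply(report$sites, strip_site),
       comparison = report$comparison, notes = report$notes,
       provenance = report$provenance)
}

#' Write a network report to JSON
#' @param report a `network_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "network_report"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_to_json_list(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a network report written by [write_report]
#' @param path JSON path.
#' @return the parsed report (plain list; matrices come back as lists).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}
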