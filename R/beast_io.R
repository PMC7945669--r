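# BEAST2 skyline XML skeletons and run post-processing: effective sample
# size of MCMC traces and Tracer-style skyline summary parsing/plotting.
# Running the MCMC itself is out of scope; the XML is a ready-to-edit
# skeleton targeting the BEAST 2.6 element layout, validated by
# parse-ability and round-trip extraction rather than byte equality.

#' BEAST2 run configuration
#'
#' @param mutation_rate strict-clock rate in substitutions/site/year (> 0).
#'   The rate is a plain user input; taxon-specific calibration (e.g. from
#'   body mass) is up to the user.
#' @param chain_length MCMC chain length in states (default 1e7).
#' @param log_every log interval in states (default 1000).
#' @param skyline_groups number of coalescent skyline groups (default 5).
#' @param substitution_model `"HKY"` (default, with empirical base
#'   frequencies) or `"JC69"`. The default is a package choice, not a
#'   mandated model.
#' @param output_stem stem for the trace/tree log file names.
#' @return object of class `beast_run_config`.
#' @export
beast_run_config <- function(mutation_rate, chain_length = 1e7,
                             log_every = 1000, skyline_groups = 5,
                             substitution_model = c("HKY", "JC69"),
                             output_stem = "beast_run") {
  substitution_model <- match.arg(substitution_model)
  if (!is.numeric(mutation_rate) || mutation_rate <= 0)
    stop("mutation_rate must be > 0")
  if (chain_length <= 0) stop("chain_length must be > 0")
  if (skyline_groups < 1) stop("skyline_groups must be >= 1")
  if (log_every <= 0) stop("log_every must be > 0")
  structure(list(mutation_rate = mutation_rate,
                 chain_length = as.numeric(chain_length),
                 log_every = as.integer(log_every),
                 skyline_groups = as.integer(skyline_groups),
                 substitution_model = substitution_model,
                 output_stem = output_stem),
            class = "beast_run_config")
}

fmt_int <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Build a Bayesian-skyline BEAST2 XML skeleton
#'
#' Emits a well-formed BEAST2 document containing the alignment verbatim, a
#' strict clock at the configured rate, a coalescent Bayesian skyline tree
#' prior with the configured group count, and an MCMC element with trace and
#' tree loggers named after `output_stem`. The alignment must be gap-free
#' and unambiguous (run [remove_ambiguous_columns()] first).
#'
#' @param aln a cleaned `mt_alignment`.
#' @param cfg a `beast_run_config`.
#' @return an `xml2::xml_document`.
#' @export
setup_basic_xml <- function(aln, cfg) {
  stopifnot(inherits(aln, "mt_alignment"), inherits(cfg, "beast_run_config"))
  bad <- vapply(aln$matrix, function(r)
    any(!strsplit(r, "", fixed = TRUE)[[1]] %in% c("A", "C", "G", "T")),
    logical(1))
  if (any(bad))
    stop("alignment contains gaps/ambiguities; clean it before XML export")
  doc <- xml2::xml_new_root(
    "beast", version = "2.6",
    namespace = paste("beast.core", "beast.evolution.alignment",
                      "beast.evolution.tree.coalescent", "beast.core.util",
                      "beast.evolution.operators", "beast.evolution.sitemodel",
                      "beast.evolution.substitutionmodel",
                      "beast.evolution.branchratemodel",
                      "beast.evolution.likelihood", sep = ":"))
  data <- xml2::xml_add_child(doc, "data", id = "alignment",
                              spec = "Alignment", dataType = "nucleotide")
  for (i in seq_along(aln$seq_ids)) {
    xml2::xml_add_child(data, "sequence",
                        id = paste0("seq_", aln$seq_ids[[i]]),
                        spec = "Sequence", taxon = aln$seq_ids[[i]],
                        totalcount = "4", value = aln$matrix[[i]])
  }
  run <- xml2::xml_add_child(doc, "run", id = "mcmc", spec = "MCMC",
                             chainLength = fmt_int(cfg$chain_length))
  state <- xml2::xml_add_child(run, "state", id = "state", storeEvery = "5000")
  xml2::xml_add_child(state, "tree", id = "Tree.t", spec = "beast.evolution.tree.Tree",
                      taxonset = "@alignment")
  pop <- xml2::xml_add_child(state, "parameter", id = "bPopSizes.t",
                             spec = "parameter.RealParameter",
                             dimension = fmt_int(cfg$skyline_groups),
                             lower = "0.0", name = "stateNode")
  xml2::xml_set_text(pop, "380.0")
  grp <- xml2::xml_add_child(state, "stateNode", id = "bGroupSizes.t",
                             spec = "parameter.IntegerParameter",
                             dimension = fmt_int(cfg$skyline_groups))
  xml2::xml_set_text(grp, "1")
  if (cfg$substitution_model == "HKY") {
    kap <- xml2::xml_add_child(state, "parameter", id = "kappa.s",
                               spec = "parameter.RealParameter",
                               lower = "0.0", name = "stateNode")
    xml2::xml_set_text(kap, "2.0")
  }
  post <- xml2::xml_add_child(run, "distribution", id = "posterior",
                              spec = "util.CompoundDistribution")
  prior <- xml2::xml_add_child(post, "distribution", id = "prior",
                               spec = "util.CompoundDistribution")
  sky <- xml2::xml_add_child(prior, "distribution", id = "BayesianSkyline.t",
                             spec = "BayesianSkyline",
                             groupSizes = "@bGroupSizes.t",
                             popSizes = "@bPopSizes.t")
  xml2::xml_add_child(sky, "treeIntervals", id = "TreeIntervals.t",
                      spec = "TreeIntervals", tree = "@Tree.t")
  lik <- xml2::xml_add_child(post, "distribution", id = "likelihood",
                             spec = "util.CompoundDistribution")
  tl <- xml2::xml_add_child(lik, "distribution", id = "treeLikelihood",
                            spec = "ThreadedTreeLikelihood", data = "@alignment",
                            tree = "@Tree.t")
  site <- xml2::xml_add_child(tl, "siteModel", id = "SiteModel.s",
                              spec = "SiteModel")
  if (cfg$substitution_model == "HKY") {
    subst <- xml2::xml_add_child(site, "substModel", id = "hky.s",
                                 spec = "HKY", kappa = "@kappa.s")
    xml2::xml_add_child(subst, "frequencies", id = "empiricalFreqs.s",
                        spec = "Frequencies", data = "@alignment")
  } else {
    xml2::xml_add_child(site, "substModel", id = "JC69.s",
                        spec = "JukesCantor")
  }
  clock <- xml2::xml_add_child(tl, "branchRateModel", id = "StrictClock.c",
                               spec = "beast.evolution.branchratemodel.StrictClockModel")
  rate <- xml2::xml_add_child(clock, "parameter", id = "clockRate.c",
                              spec = "parameter.RealParameter",
                              estimate = "false", name = "clock.rate")
  # 17 significant digits so the rate survives the text round trip exactly
  xml2::xml_set_text(rate, format(cfg$mutation_rate, digits = 17))
  # operators: minimal standard set for a skyline analysis
  xml2::xml_add_child(run, "operator", id = "treeScaler.t", spec = "ScaleOperator",
                      scaleFactor = "0.5", tree = "@Tree.t", weight = "3.0")
  xml2::xml_add_child(run, "operator", id = "popSizesScaler.t", spec = "ScaleOperator",
                      parameter = "@bPopSizes.t", scaleFactor = "0.75", weight = "15.0")
  xml2::xml_add_child(run, "operator", id = "groupSizesDelta.t",
                      spec = "DeltaExchangeOperator", integer = "true",
                      parameter = "@bGroupSizes.t", weight = "6.0")
  trace <- xml2::xml_add_child(run, "logger", id = "tracelog",
                               fileName = paste0(cfg$output_stem, ".log"),
                               logEvery = fmt_int(cfg$log_every))
  xml2::xml_add_child(trace, "log", idref = "posterior")
  xml2::xml_add_child(trace, "log", idref = "BayesianSkyline.t")
  treelog <- xml2::xml_add_child(run, "logger", id = "treelog",
                                 fileName = paste0(cfg$output_stem, ".trees"),
                                 logEvery = fmt_int(cfg$log_every), mode = "tree")
  xml2::xml_add_child(treelog, "log", idref = "Tree.t")
  screen <- xml2::xml_add_child(run, "logger", id = "screenlog",
                                logEvery = fmt_int(cfg$log_every))
  xml2::xml_add_child(screen, "log", idref = "posterior")
  doc
}

#' Extract the key fields back out of a BEAST2 XML document
#'
#' Round-trip accessor used to verify that sequences, taxon labels, clock
#' rate and chain length survive XML emission verbatim.
#'
#' @param doc an `xml2::xml_document` (or path to one).
#' @return list with `sequences` (named character vector), `taxa`,
#'   `clock_rate`, `chain_length`, `log_files`.
#' @export
beast_xml_info <- function(doc) {
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  seq_nodes <- xml2::xml_find_all(doc, ".//data/sequence")
  seqs <- setNames(xml2::xml_attr(seq_nodes, "value"),
                   xml2::xml_attr(seq_nodes, "taxon"))
  run <- xml2::xml_find_first(doc, ".//run")
  rate_node <- xml2::xml_find_first(doc, ".//parameter[@name='clock.rate']")
  loggers <- xml2::xml_find_all(doc, ".//logger[@fileName]")
  list(sequences = seqs, taxa = names(seqs),
       clock_rate = as.numeric(xml2::xml_text(rate_node)),
       chain_length = as.numeric(xml2::xml_attr(run, "chainLength")),
       log_files = xml2::xml_attr(loggers, "fileName"))
}

#' An MCMC trace with burn-in
#'
#' @param values numeric vector of sampled states.
#' @param name parameter name.
#' @param burn_in fraction of the chain to discard (default 0.1; must be in
#'   `[0, 1)`). At least 10 samples must remain.
#' @return object of class `trace_series`.
#' @export
trace_series <- function(values, name = "parameter", burn_in = 0.1) {
  stopifnot(is.numeric(values))
  if (burn_in < 0 || burn_in >= 1) stop("burn_in must be in [0, 1)")
  retained <- values[(floor(length(values) * burn_in) + 1L):length(values)]
  if (length(retained) < 10L)
    stop("fewer than 10 samples retained after burn-in")
  structure(list(name = name, values = retained, burn_in = burn_in),
            class = "trace_series")
}

#' Read a BEAST trace log
#'
#' Tab-delimited with `#`-prefixed comment lines, one column per logged
#' parameter.
#'
#' @param path path to the `.log` file.
#' @return data frame of sampled values.
#' @export
read_trace_log <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE)
}

#' Effective sample size of an MCMC trace
#'
#' `ESS = n / (1 + 2 * sum(rho_k))`, with the autocorrelation sum truncated
#' by the initial-positive-sequence rule (consecutive pairs of
#' autocorrelations are added while their sum stays positive). The
#' integrated autocorrelation time is clamped to >= 1 so ESS never exceeds
#' `n`; a constant series returns ESS = 1 by convention. Values below 200
#' are flagged: such runs need more states or better mixing before their
#' skyline output should be trusted.
#'
#' @param tr a `trace_series`, or a numeric vector (>= 10 values, no
#'   burn-in applied).
#' @param warn_below flag threshold (default 200).
#' @return numeric ESS with attributes `low_ess` (logical) and `n`.
#' @export
effective_sample_size <- function(tr, warn_below = 200) {
  v <- if (inherits(tr, "trace_series")) tr$values else as.numeric(tr)
  n <- length(v)
  if (n < 10L) stop("need at least 10 samples for an ESS estimate")
  if (var(v) == 0) {
    return(structure(1, low_ess = TRUE, n = n))
  }
  rho <- acf_fft(v)
  # Geyer initial positive sequence: Gamma_m = rho_{2m} + rho_{2m+1}
  tau <- 0
  m <- 0L
  max_m <- floor((n - 2L) / 2L)
  while (m <= max_m) {
    g <- rho[[2L * m + 1L]] + rho[[2L * m + 2L]]
    if (g <= 0) break
    tau <- tau + g
    m <- m + 1L
  }
  tau <- max(2 * tau - 1, 1)
  ess <- n / tau
  structure(ess, low_ess = ess < warn_below, n = n)
}

# Autocorrelation function rho_0..rho_{n-1} via FFT.
acf_fft <- function(v) {
  n <- length(v)
  x <- v - mean(v)
  m <- 2^ceiling(log2(2 * n))
  f <- fft(c(x, rep(0, m - n)))
  ac <- Re(fft(f * Conj(f), inverse = TRUE))[seq_len(n)]
  ac / ac[[1]]
}

#' Parse a Tracer-style skyline summary table
#'
#' Delimited text with (case-insensitive) `time`, `median`, `upper` and
#' `lower` columns, as exported from a skyline reconstruction. Rows are
#' validated: `lower <= median <= upper` and strictly increasing times.
#'
#' @param path path to the summary table (tab- or comma-delimited).
#' @return a `skyline_profile` data frame with columns `time`, `median`,
#'   `lower`, `upper`.
#' @export
parse_skyline_summary <- function(path) {
  if (!file.exists(path)) stop("skyline summary not found: ", path)
  first <- readLines(path, n = 2L, warn = FALSE)
  sep <- if (grepl("\t", first[[1]])) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  nm <- tolower(names(tab))
  cols <- c(time = "time", median = "median", upper = "upper", lower = "lower")
  idx <- setNames(match(cols, nm), names(cols))
  if (anyNA(idx))
    stop("skyline summary is missing column(s): ",
         paste(cols[is.na(idx)], collapse = ", "))
  prof <- data.frame(time = as.numeric(tab[[idx[["time"]]]]),
                     median = as.numeric(tab[[idx[["median"]]]]),
                     lower = as.numeric(tab[[idx[["lower"]]]]),
                     upper = as.numeric(tab[[idx[["upper"]]]]))
  if (!nrow(prof)) {
    warning("skyline summary has a header but no rows: ", path)
    return(structure(prof, class = c("skyline_profile", "data.frame")))
  }
  bad <- which(prof$lower > prof$median | prof$median > prof$upper)
  if (length(bad))
    stop("skyline summary violates lower <= median <= upper at row ", bad[[1]])
  if (any(diff(prof$time) <= 0))
    stop("skyline summary times must be strictly increasing")
  structure(prof, class = c("skyline_profile", "data.frame"))
}

#' Write a skyline profile back to a Tracer-style table
#'
#' Inverse of [parse_skyline_summary()] on valid profiles.
#'
#' @param profile a `skyline_profile`.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_skyline_summary <- function(profile, path) {
  tab <- data.frame(Time = profile$time, Median = profile$median,
                    Upper = profile$upper, Lower = profile$lower)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a skyline profile
#'
#' Median effective population size as a dashed line with the 95% HPD
#' envelope shaded, time before present on the x axis.
#'
#' @param x a `skyline_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.skyline_profile <- function(x, ...) {
  plot(x$time, x$median, type = "n", ylim = range(c(x$lower, x$upper)),
       xlab = "Time before present (years)", ylab = expression(N[e]),
       main = "Bayesian skyline profile", ...)
  polygon(c(x$time, rev(x$time)), c(x$lower, rev(x$upper)),
          col = adjustcolor("steelblue", 0.3), border = NA)
  lines(x$time, x$median, lty = 2, lwd = 2)
  invisible(x)
}
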