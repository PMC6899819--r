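# Arm-level NMA data container and validation.
#
# A network is stored as a flat table of arms (one row per treatment group)
# plus derived bookkeeping: the number of studies n, the number of
# treatments K, and the per-study designs R_i (the set of treatments
# compared in study i).  Treatments are relabeled to dense integers 1..K;
# the relabeling map is kept so tables can be written back with their
# original labels.

#' Construct an arm-level NMA network
#'
#' Validates and packages arm-level binary-outcome data for network
#' meta-analysis.  Each row describes one arm: the study it belongs to, the
#' treatment given, the number of events (successes) and the arm size.
#'
#' @param arms data frame with columns `study`, `treatment`, `events`,
#'   `size` (one row per arm).
#' @param reference reference treatment, given in the original labeling
#'   (default `1`, or the first treatment label if `1` is absent).
#' @return An object of class `nma_network`: a list with elements
#'   `arms` (integer-coded data frame), `n_studies`, `n_treatments`,
#'   `designs` (list of sorted integer treatment sets per study),
#'   `reference` (integer id), `treatment_labels`, `study_labels`.
#' @examples
#' net <- nma_network(data.frame(
#'   study = c(1, 1, 2, 2), treatment = c(1, 2, 1, 3),
#'   events = c(5, 9, 2, 7), size = c(50, 50, 40, 40)))
#' net$n_treatments
#' @export
nma_network <- function(arms, reference = NULL) {
  arms <- as.data.frame(arms)
  need <- c("study", "treatment", "events", "size")
  if (!all(need %in% names(arms))) {
    stop("arm table must have columns ", paste(need, collapse = ", "),
         "; missing: ", paste(setdiff(need, names(arms)), collapse = ", "))
  }
  arms <- arms[need]
  if (nrow(arms) == 0) stop("arm table is empty")
  if (anyNA(arms)) stop("arm table contains missing values")
  if (!is.numeric(arms$events) || !is.numeric(arms$size) ||
      any(arms$events != round(arms$events)) || any(arms$size != round(arms$size))) {
    stop("events and size must be integer counts")
  }
  if (any(arms$size < 1)) {
    stop("arm size must be >= 1; offending row(s): ",
         paste(which(arms$size < 1), collapse = ", "))
  }
  if (any(arms$events < 0)) {
    stop("events must be non-negative; offending row(s): ",
         paste(which(arms$events < 0), collapse = ", "))
  }
  bad <- which(arms$events > arms$size)
  if (length(bad)) {
    stop("events exceed arm size in row(s): ", paste(bad, collapse = ", "),
         " (e.g. study ", arms$study[bad[1]], ", treatment ",
         arms$treatment[bad[1]], ": ", arms$events[bad[1]], " > ",
         arms$size[bad[1]], ")")
  }

  study_labels <- as.character(unique(arms$study))
  study_id <- match(as.character(arms$study), study_labels)

  # Dense 1..K treatment coding.  Numeric labels keep their numeric order
  # (preserving an existing 1..K coding); other labels sort as characters.
  tr_raw <- arms$treatment
  tr_chr <- as.character(tr_raw)
  u <- unique(tr_chr)
  if (!anyNA(suppressWarnings(as.numeric(u)))) {
    treatment_labels <- u[order(as.numeric(u))]
  } else {
    treatment_labels <- sort(u)
  }
  treatment_id <- match(tr_chr, treatment_labels)

  if (is.null(reference)) {
    reference <- if ("1" %in% treatment_labels) "1" else treatment_labels[1]
  }
  ref_id <- match(as.character(reference), treatment_labels)
  if (is.na(ref_id)) stop("reference treatment '", reference, "' not in network")

  dup <- duplicated(paste(study_id, treatment_id))
  if (any(dup)) {
    stop("duplicate (study, treatment) pair in row(s): ",
         paste(which(dup), collapse = ", "))
  }

  coded <- data.frame(study = study_id, treatment = treatment_id,
                      events = as.integer(arms$events),
                      size = as.integer(arms$size))
  coded <- coded[order(coded$study, coded$treatment), , drop = FALSE]
  rownames(coded) <- NULL
  designs <- lapply(split(coded$treatment, coded$study), sort)
  names(designs) <- NULL
  single <- which(vapply(designs, length, 1L) < 2)
  if (length(single)) {
    stop("every study needs at least 2 arms; offending study id(s): ",
         paste(study_labels[single], collapse = ", "))
  }

  structure(list(arms = coded,
                 n_studies = length(designs),
                 n_treatments = length(treatment_labels),
                 designs = designs,
                 reference = ref_id,
                 treatment_labels = treatment_labels,
                 study_labels = study_labels),
            class = "nma_network")
}

#' @export
print.nma_network <- function(x, ...) {
  cat("nma_network:", x$n_studies, "studies,", x$n_treatments, "treatments,",
      nrow(x$arms), "arms\n")
  cat("reference treatment:", x$treatment_labels[x$reference], "\n")
  ds <- summarize_designs(x)
  cat("designs:\n")
  print(ds, row.names = FALSE)
  invisible(x)
}

#' Read an arm-level network from CSV
#'
#' The long ("flat") dialect has one row per arm with header columns
#' `study,treatment,events,size`.  The wide dialect mirrors the common
#' two-arm tabulation of an active arm alongside a reference arm, with
#' header columns
#' `study,active_treatment,active_events,active_size,ref_treatment,ref_events,ref_size`.
#'
#' @param path CSV file path.
#' @param dialect `"long"` (default) or `"wide"`.
#' @param reference passed to [nma_network()].
#' @return an [nma_network()] object.
#' @export
read_network <- function(path, dialect = c("long", "wide"), reference = NULL) {
  dialect <- match.arg(dialect)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (dialect == "wide") {
    need <- c("study", "active_treatment", "active_events", "active_size",
              "ref_treatment", "ref_events", "ref_size")
    if (!all(need %in% names(tab))) {
      stop("wide table must have columns ", paste(need, collapse = ", "))
    }
    tab <- rbind(
      data.frame(study = tab$study, treatment = tab$active_treatment,
                 events = tab$active_events, size = tab$active_size),
      data.frame(study = tab$study, treatment = tab$ref_treatment,
                 events = tab$ref_events, size = tab$ref_size))
  }
  nma_network(tab, reference = reference)
}

#' Write a network back to long-format CSV
#'
#' Columns `study,treatment,events,size` with the original labels, so that
#' `read_network()` round-trips.
#'
#' @param net an `nma_network`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "nma_network"))
  out <- data.frame(study = net$study_labels[net$arms$study],
                    treatment = net$treatment_labels[net$arms$treatment],
                    events = net$arms$events,
                    size = net$arms$size)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Inhaled corticosteroids example network
#'
#' A star network of 18 randomized trials comparing seven inhaled
#' corticosteroids against placebo in chronic asthma; the binary outcome is
#' elimination of oral corticosteroid use.  Treatments are coded 1 placebo,
#' 2 beclomethasone, 3 budesonide, 4 ciclesonide, 5 flunisolide,
#' 6 fluticasone, 7 mometasone, 8 triamcinolone.  Four placebo arms have
#' zero events; the exact binomial likelihood used throughout the package
#' handles these without continuity corrections.
#'
#' @return an [nma_network()] with 18 studies, 8 treatments and 36 arms.
#' @export
corticosteroids <- function() {
  path <- system.file("extdata", "corticosteroids.csv", package = "abnma",
                      mustWork = TRUE)
  read_network(path, reference = 1)
}

#' Tabulate study designs
#'
#' @param net an `nma_network`.
#' @return data frame with one row per distinct design: `design` (treatment
#'   ids joined by `+`) and `count`; counts sum to the number of studies.
#' @export
summarize_designs <- function(net) {
  stopifnot(inherits(net, "nma_network"))
  keys <- vapply(net$designs, function(d) paste(d, collapse = "+"), "")
  tab <- table(keys)
  out <- data.frame(design = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(out$design), , drop = FALSE]
}

#' Is the network a star?
#'
#' A star network compares every non-reference treatment only against the
#' common reference: every study design contains the reference treatment.
#'
#' @param net an `nma_network`.
#' @return `TRUE` iff every design contains `net$reference`.
#' @export
is_star <- function(net) {
  stopifnot(inherits(net, "nma_network"))
  all(vapply(net$designs, function(d) net$reference %in% d, TRUE))
}

#' Count zero-event arms of a treatment
#'
#' @param net an `nma_network`.
#' @param treatment integer treatment id (1..K).
#' @return number of arms of that treatment with zero events.
#' @export
count_zero_event_arms <- function(net, treatment) {
  stopifnot(inherits(net, "nma_network"))
  if (!treatment %in% net$arms$treatment) {
    stop("treatment ", treatment, " not present in network")
  }
  sum(net$arms$treatment == treatment & net$arms$events == 0)
}

#' L'Abbe plot coordinates
#'
#' Observed event fractions per study on the reference arm (x) and the other
#' arm (y), for two-arm networks.  Useful for eyeballing variation in
#' underlying risk and treatment effect.
#'
#' @param net an `nma_network` of two-arm studies each containing the
#'   reference treatment.
#' @return data frame with columns `study`, `treatment` (the non-reference
#'   arm's id), `ref_frac`, `other_frac`, ordered by study id.
#' @export
labbe_points <- function(net) {
  stopifnot(inherits(net, "nma_network"))
  n_arm <- vapply(net$designs, length, 1L)
  if (any(n_arm != 2)) {
    stop("labbe_points needs two-arm studies; offending study id(s): ",
         paste(net$study_labels[n_arm != 2], collapse = ", "))
  }
  no_ref <- !vapply(net$designs, function(d) net$reference %in% d, TRUE)
  if (any(no_ref)) {
    stop("study without reference arm: ",
         paste(net$study_labels[no_ref], collapse = ", "))
  }
  a <- net$arms
  ref <- a[a$treatment == net$reference, ]
  oth <- a[a$treatment != net$reference, ]
  ref <- ref[order(ref$study), ]
  oth <- oth[order(oth$study), ]
  data.frame(study = net$study_labels[ref$study],
             treatment = oth$treatment,
             ref_frac = ref$events / ref$size,
             other_frac = oth$events / oth$size)
}
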