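#' Construct a cohort dataset
#'
#' A cohort holds aligned subjects: per-modality edge weights (upper-triangle
#' vectorized), the behavior score (sway area in cm^2, positive; smaller =
#' better balance), covariates (age in years, sex coded 0/1, arbitrary
#' extras such as mean framewise displacement), and an optional secondary
#' behavior (rate of torque development, N·m/s) used for specificity tests.
#'
#' @param edges named list, one entry per modality (`functional`,
#'   `structural`); each an `n_subjects x n_edges` numeric matrix in the
#'   canonical order of [edge_index()].
#' @param behavior positive numeric vector, one score per subject.
#' @param atlas a [cpm_atlas()] object; its node count must match the edge
#'   dimension.
#' @param subjects subject identifiers (unique).
#' @param covariates data frame of numeric covariates (may have 0 columns).
#' @param secondary optional secondary behavior; `NA` where missing.
#' @param timepoint label, e.g. `"tp1"` or `"tp2"`.
#' @return An object of class `cpm_cohort`.
#' @export
cpm_cohort <- function(edges, behavior, atlas,
                       subjects = NULL, covariates = NULL,
                       secondary = NULL, timepoint = "tp1") {
  if (!inherits(atlas, "cpm_atlas")) stop("atlas must be a cpm_atlas")
  if (!is.list(edges) || is.null(names(edges)) || any(names(edges) == ""))
    stop("edges must be a named list of modality matrices")
  bad <- setdiff(names(edges), c("functional", "structural"))
  if (length(bad)) stop("unknown modality: ", paste(bad, collapse = ", "))
  edges <- lapply(edges, as.matrix)
  n <- nrow(edges[[1L]])
  n_nodes <- nrow(atlas)
  n_edges <- n_nodes * (n_nodes - 1L) / 2L
  for (mod in names(edges)) {
    e <- edges[[mod]]
    if (nrow(e) != n) stop("modalities disagree on subject count")
    if (ncol(e) != n_edges)
      stop(sprintf("%s edge matrix has %d columns; atlas implies %d",
                   mod, ncol(e), n_edges))
    if (any(!is.finite(e))) stop("non-finite edge weights in ", mod)
  }
  behavior <- as.numeric(behavior)
  if (length(behavior) != n) stop("one behavior score per subject required")
  if (any(!is.finite(behavior))) stop("behavior scores must be non-missing")
  if (is.null(subjects)) subjects <- sprintf("s%03d", seq_len(n))
  subjects <- as.character(subjects)
  if (anyDuplicated(subjects)) stop("subject ids must be unique")
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_len(n))
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) stop("covariates must have one row per subject")
  if (ncol(covariates) && any(!vapply(covariates, is.numeric, logical(1L))))
    stop("covariates must be numeric (code sex as 0/1)")
  if (ncol(covariates) && any(is.na(covariates)))
    stop("covariates must be non-missing for included subjects")
  if (!is.null(secondary)) {
    secondary <- as.numeric(secondary)
    if (length(secondary) != n) stop("secondary behavior length mismatch")
  }
  structure(list(edges = edges, behavior = behavior, atlas = atlas,
                 subjects = subjects, covariates = covariates,
                 secondary = secondary, timepoint = timepoint,
                 n_nodes = n_nodes),
            class = "cpm_cohort")
}

#' @export
print.cpm_cohort <- function(x, ...) {
  cat(sprintf("Connectome cohort (%s): %d subjects, %d nodes (%d edges)\n",
              x$timepoint, length(x$subjects), x$n_nodes,
              x$n_nodes * (x$n_nodes - 1L) / 2L))
  cat(sprintf("  modalities: %s\n", paste(names(x$edges), collapse = ", ")))
  cat(sprintf("  behavior (sway area, cm^2): median %.2f [%.2f, %.2f]\n",
              stats::median(x$behavior), min(x$behavior), max(x$behavior)))
  if (ncol(x$covariates))
    cat(sprintf("  covariates: %s\n", paste(names(x$covariates), collapse = ", ")))
  if (!is.null(x$secondary))
    cat(sprintf("  secondary behavior present for %d subjects\n",
                sum(is.finite(x$secondary))))
  invisible(x)
}

#' Number of subjects in a cohort
#' @param x a `cpm_cohort`.
#' @return Integer subject count.
#' @export
n_subjects <- function(x) length(x$subjects)

#' Subset a cohort by subject
#' @param x a `cpm_cohort`.
#' @param i subject indices or ids.
#' @param ... unused.
#' @return A `cpm_cohort` with the selected subjects.
#' @export
`[.cpm_cohort` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$subjects)
  if (any(is.na(i))) stop("unknown subject id(s)")
  cpm_cohort(lapply(x$edges, function(e) e[i, , drop = FALSE]),
             x$behavior[i], x$atlas, subjects = x$subjects[i],
             covariates = x$covariates[i, , drop = FALSE],
             secondary = if (!is.null(x$secondary)) x$secondary[i],
             timepoint = x$timepoint)
}

#' Load a cohort from delimited text files
#'
#' Reads per-subject connectome matrices plus a cohort table and assembles a
#' [cpm_cohort()]. Subjects with a missing required field (behavior or any
#' requested covariate) are excluded with a logged reason, as are subjects
#' failing any declarative exclusion filter (e.g. `"mean_fd <= 0.3"`, the
#' head-motion rule: subjects with mean framewise displacement above 0.3 mm
#' are dropped).
#'
#' @param matrix_paths data frame with columns `subject_id`, `modality`
#'   (`functional`/`structural`), `path`.
#' @param cohort_table path to a delimited file with header (columns
#'   `subject_id`, `behavior`; optional `age`, `sex`, `timepoint`,
#'   `secondary_behavior`, extra covariates), or an equivalent data frame.
#' @param atlas a [cpm_atlas()].
#' @param covariates covariate column names that must be present and
#'   non-missing.
#' @param filters character vector of predicates evaluated on the cohort
#'   table; a subject is kept only if every predicate is `TRUE`.
#' @param tol asymmetry tolerance passed to [ingest_connectome()].
#' @return A `cpm_cohort`; excluded subjects and reasons are in the
#'   `exclusions` attribute and reported via `message()`.
#' @export
load_cohort <- function(matrix_paths, cohort_table, atlas,
                        covariates = c("age", "sex"),
                        filters = character(), tol = 1e-6) {
  tab <- if (is.character(cohort_table))
    utils::read.table(cohort_table, header = TRUE,
                      sep = detect_sep(cohort_table),
                      stringsAsFactors = FALSE)
  else as.data.frame(cohort_table)
  if (!all(c("subject_id", "behavior") %in% names(tab)))
    stop("cohort table needs subject_id and behavior columns")
  tab$subject_id <- as.character(tab$subject_id)

  keep <- rep(TRUE, nrow(tab))
  reasons <- character(nrow(tab))
  mark <- function(drop, why) {
    newly <- drop & keep
    reasons[newly] <<- why
    keep <<- keep & !drop
  }
  mark(!is.finite(tab$behavior), "missing behavior")
  for (cv in covariates) {
    if (!cv %in% names(tab)) stop("covariate column not in table: ", cv)
    mark(!is.finite(tab[[cv]]), paste("missing covariate", cv))
  }
  for (f in filters) {
    ok <- eval(parse(text = f), tab)
    mark(!(ok %in% TRUE), paste("failed filter:", f))
  }
  mods <- unique(as.character(matrix_paths$modality))
  for (mod in mods) {
    has <- tab$subject_id %in%
      matrix_paths$subject_id[matrix_paths$modality == mod]
    mark(!has, paste("no", mod, "matrix"))
  }
  excl <- data.frame(subject_id = tab$subject_id[!keep],
                     reason = reasons[!keep], stringsAsFactors = FALSE)
  for (k in seq_len(nrow(excl)))
    message(sprintf("excluding subject %s: %s",
                    excl$subject_id[k], excl$reason[k]))
  tab <- tab[keep, , drop = FALSE]
  if (!nrow(tab)) stop("no subjects left after exclusions")

  n_nodes <- nrow(atlas)
  edges <- lapply(stats::setNames(mods, mods), function(mod) {
    unname(t(vapply(tab$subject_id, function(sid) {
      p <- matrix_paths$path[matrix_paths$subject_id == sid &
                               matrix_paths$modality == mod][1L]
      matrix_to_edges(read_connectome(p, n_nodes, tol = tol,
                                      nonnegative = mod == "structural"))
    }, numeric(n_nodes * (n_nodes - 1L) / 2L))))
  })
  cov_df <- tab[, intersect(covariates, names(tab)), drop = FALSE]
  out <- cpm_cohort(edges, tab$behavior, atlas,
                    subjects = tab$subject_id, covariates = cov_df,
                    secondary = if ("secondary_behavior" %in% names(tab))
                      tab$secondary_behavior,
                    timepoint = if ("timepoint" %in% names(tab))
                      as.character(tab$timepoint[1L]) else "tp1")
  attr(out, "exclusions") <- excl
  out
}

#' Write a cohort to delimited text files
#'
#' Emits the same on-disk layout [load_cohort()] reads: one matrix file per
#' subject/modality (`<subject>_<modality>.txt`, full precision), a
#' `cohort.csv` table and an `atlas.csv`.
#'
#' @param cohort a `cpm_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the `matrix_paths` data frame suitable for
#'   [load_cohort()].
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- expand.grid(subject_id = cohort$subjects,
                       modality = names(cohort$edges),
                       stringsAsFactors = FALSE)
  paths$path <- file.path(dir, sprintf("%s_%s.txt", paths$subject_id,
                                       paths$modality))
  for (k in seq_len(nrow(paths))) {
    i <- match(paths$subject_id[k], cohort$subjects)
    m <- edges_to_matrix(cohort$edges[[paths$modality[k]]][i, ],
                         cohort$n_nodes)
    chr <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
    utils::write.table(chr, paths$path[k], row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  tab <- data.frame(subject_id = cohort$subjects,
                    behavior = cohort$behavior,
                    timepoint = cohort$timepoint,
                    stringsAsFactors = FALSE)
  if (ncol(cohort$covariates)) tab <- cbind(tab, cohort$covariates)
  if (!is.null(cohort$secondary)) tab$secondary_behavior <- cohort$secondary
  utils::write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE,
                   quote = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.csv"))
  invisible(paths)
}
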