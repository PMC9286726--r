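## Plain-text I/O with provenance headers. Every writer prefixes '# key: value'
## comment lines (package version, config hash, seed) so outputs are
## self-describing; no timestamps, so reruns are byte-identical.

tn_config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  h <- 0
  for (v in utf8ToInt(txt)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

tn_header_lines <- function(provenance = list()) {
  base <- list(package = paste0("trinetdyn ",
                                as.character(utils::packageVersion("trinetdyn"))))
  prov <- c(base, provenance)
  sprintf("# %s: %s", names(prov), vapply(prov, as.character, character(1)))
}

tn_write_table <- function(df, path, sep, provenance = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tn_header_lines(provenance), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

tn_read_table <- function(path, sep) {
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

tn_read_header <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "# ")]
  kv <- regmatches(lines, regexec("^# ([^:]+): (.*)$", lines))
  kv <- kv[lengths(kv) == 3L]
  stats::setNames(lapply(kv, `[[`, 3L), vapply(kv, `[[`, 2L, FUN.VALUE = ""))
}

#' Write / read one subject's network time series as TSV
#'
#' Four named columns (SN, LFPN, RFPN, DMN), one row per TR, preceded by
#' provenance comment lines carrying the group label and TR so the file
#' round-trips without a sidecar.
#'
#' @param ts a [network_ts()].
#' @param path output file path.
#' @param provenance named list of extra header fields.
#' @return `path`, invisibly (`write_subject_ts`); a [network_ts()]
#'   (`read_subject_ts`).
#' @export
write_subject_ts <- function(ts, path, provenance = list()) {
  stopifnot(inherits(ts, "tn_network_ts"))
  prov <- c(list(group = attr(ts, "group"), TR = attr(ts, "TR")), provenance)
  df <- as.data.frame(unclass(ts))
  names(df) <- tn_networks
  tn_write_table(df, path, sep = "\t", provenance = prov)
}

#' @param path file written by [write_subject_ts()].
#' @rdname write_subject_ts
#' @export
read_subject_ts <- function(path) {
  if (!file.exists(path)) stop("missing subject file: ", path)
  hdr <- tn_read_header(path)
  df <- tn_read_table(path, sep = "\t")
  stopifnot(all(tn_networks %in% names(df)))
  network_ts(as.matrix(df[tn_networks]),
             group = if (is.null(hdr$group)) NA_character_ else hdr$group,
             TR = if (is.null(hdr$TR)) 2.3 else as.numeric(hdr$TR))
}

#' Write windowed Fisher-z correlations as TSV plus JSON sidecar
#'
#' One row per window (`center` + the six z values in fixed pair order);
#' the sidecar records the window spec and TR.
#'
#' @param windows a `tn_windows` object.
#' @param path output TSV path; the sidecar is `<path>.json`.
#' @param provenance named list of extra header fields.
#' @return `path`, invisibly.
#' @export
write_windows <- function(windows, path, provenance = list()) {
  stopifnot(inherits(windows, "tn_windows"))
  df <- data.frame(center = windows$centers, windows$z6, check.names = FALSE)
  tn_write_table(df, path, sep = "\t", provenance = provenance)
  jsonlite::write_json(list(length_L = windows$spec$length_L,
                            decay_theta = windows$spec$decay_theta,
                            step = windows$spec$step, TR = windows$TR),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param path TSV written by [write_windows()].
#' @rdname write_windows
#' @export
read_windows <- function(path) {
  df <- tn_read_table(path, sep = "\t")
  side <- jsonlite::read_json(paste0(path, ".json"))
  spec <- window_spec(side$length_L, side$decay_theta, side$step)
  z6 <- as.matrix(df[, tn_pairs])
  structure(list(centers = df$center, corr = NULL, z6 = z6, spec = spec,
                 TR = if (is.null(side$TR)) NULL else as.numeric(side$TR)),
            class = "tn_windows")
}

#' Write a simulated cohort to disk
#'
#' Emits per-subject time-series TSVs, a cohort manifest CSV
#' (`subject_id`, `group`, `seed`, `file`), and a ground-truth JSON holding
#' each subject's hidden state sequence and each state's true NII.
#'
#' @param subjects output of [simulate_cohort()].
#' @param cohort the generating [cohort_spec()].
#' @param dir output directory (created if needed).
#' @param provenance named list of extra header fields.
#' @return the manifest data frame, invisibly.
#' @export
write_cohort <- function(subjects, cohort, dir, provenance = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- attr(subjects, "subject_seeds")
  files <- file.path(dir, paste0(names(subjects), ".tsv"))
  for (i in seq_along(subjects)) {
    write_subject_ts(subjects[[i]], files[i], provenance = provenance)
  }
  manifest <- data.frame(subject_id = names(subjects),
                         group = cohort$group_name, seed = seeds,
                         file = basename(files), stringsAsFactors = FALSE)
  tn_write_table(manifest, file.path(dir, "manifest.csv"), sep = ",",
                 provenance = provenance)
  truth <- list(group = cohort$group_name, p_self = cohort$p_self,
                TR = cohort$TR,
                true_nii = vapply(cohort$states, `[[`, numeric(1),
                                  "true_nii"),
                state_seq = lapply(subjects, function(s)
                  attr(s, "state_seq", exact = TRUE)))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.csv`.
#' @return named list of [network_ts()] objects.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir)
  manifest <- tn_read_table(mpath, sep = ",")
  subjects <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(dir, manifest$file[i])
    if (!file.exists(f)) {
      stop(sprintf("missing subject file for manifest row %d (%s): %s",
                   i, manifest$subject_id[i], f))
    }
    subjects[[i]] <- read_subject_ts(f)
  }
  names(subjects) <- manifest$subject_id
  subjects
}

#' Write a group state partition as JSON plus per-subject label TSV
#'
#' @param partition a `tn_group_partition`.
#' @param dir output directory.
#' @param provenance named list of extra header fields.
#' @return `dir`, invisibly.
#' @export
write_partition <- function(partition, dir, provenance = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- partition$group_name
  jsonlite::write_json(
    list(group = g, k = partition$k_selected,
         index_votes = as.list(partition$index_votes),
         centroids = partition$centroids),
    file.path(dir, paste0(g, "_partition.json")),
    auto_unbox = TRUE, digits = NA)
  labs <- do.call(rbind, lapply(names(partition$labels), function(id)
    data.frame(subject_id = id, window = seq_along(partition$labels[[id]]),
               state = partition$labels[[id]])))
  tn_write_table(labs, file.path(dir, paste0(g, "_labels.tsv")), sep = "\t",
                 provenance = provenance)
  invisible(dir)
}
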