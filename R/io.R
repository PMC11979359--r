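#' Write a cohort to disk as plain-text files
#'
#' Per subject and sequence: a tab-separated time x region matrix
#' (`sub-XXX_seq-Q_bold.tsv`, header = region labels) and a
#' confounds-style TSV (`sub-XXX_seq-Q_confounds.tsv` with columns
#' trans_x..rot_z and framewise_displacement, FWD padded with a leading
#' zero); one behavior CSV; and a YAML manifest listing files, sequence
#' order, and TR.
#'
#' @param cohort a `gs_cohort`.
#' @param dir output directory (created if needed).
#' @return path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gs_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tr_seconds = cohort$spec$tr_seconds,
                   sequence_lengths = as.integer(cohort$spec$sequence_lengths),
                   n_regions = cohort$spec$n_regions,
                   seed = cohort$spec$seed,
                   behavior = "behavior.csv",
                   subjects = list())
  for (s in seq_along(cohort$bold)) {
    sid <- sprintf("sub-%03d", s)
    files <- list()
    for (q in seq_along(cohort$bold[[s]])) {
      bold_f <- sprintf("%s_seq-%d_bold.tsv", sid, q)
      conf_f <- sprintf("%s_seq-%d_confounds.tsv", sid, q)
      utils::write.table(cohort$bold[[s]][[q]], file.path(dir, bold_f),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      mo <- cohort$motion[[s]][[q]]
      conf <- data.frame(mo$params,
                         framewise_displacement = c(0, mo$fwd))
      utils::write.table(conf, file.path(dir, conf_f), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      files[[q]] <- list(sequence = q, bold = bold_f, confounds = conf_f)
    }
    manifest$subjects[[sid]] <- files
  }
  utils::write.csv(cohort$behavior, file.path(dir, "behavior.csv"),
                   row.names = FALSE)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.yaml`.
#' @return list with `bold`, `motion`, `behavior`, `tr_seconds`,
#'   `sequence_lengths`.
#' @export
read_cohort <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  subjects <- names(manifest$subjects)
  bold <- vector("list", length(subjects))
  motion <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    entries <- manifest$subjects[[subjects[i]]]
    bold[[i]] <- lapply(entries, function(e)
      as.matrix(utils::read.table(file.path(dir, e$bold), header = TRUE,
                                  sep = "\t", check.names = FALSE)))
    motion[[i]] <- lapply(entries, function(e) {
      conf <- utils::read.table(file.path(dir, e$confounds), header = TRUE,
                                sep = "\t")
      list(fwd = conf$framewise_displacement[-1L],
           params = as.matrix(conf[, c("trans_x", "trans_y", "trans_z",
                                       "rot_x", "rot_y", "rot_z")]))
    })
  }
  list(bold = bold, motion = motion,
       behavior = utils::read.csv(file.path(dir, manifest$behavior),
                                  check.names = FALSE),
       tr_seconds = manifest$tr_seconds,
       sequence_lengths = unlist(manifest$sequence_lengths))
}

#' Write per-scale FC and variance tables as CSV
#'
#' Long-format schemas `(region_i, region_j, scale, r, z, df)` for FC
#' and `(region, scale, variance, log_variance)` for variance, for one
#' time x region matrix.
#'
#' @param data time x region matrix.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @param scales wavelet scales.
#' @return invisibly, the two file paths.
#' @export
write_fc_tables <- function(data, dir, prefix = "seq", scales = 3:5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- modwt(as.matrix(data), max(scales), warn_boundary = FALSE)
  fc_rows <- list(); var_rows <- list()
  for (s in scales) {
    R <- wavelet_cor_matrix(d, s)
    df <- attr(R, "df")
    ut <- which(upper.tri(R), arr.ind = TRUE)
    z <- atanh(pmin(pmax(R[ut], -1 + 1e-15), 1 - 1e-15)) *
      sqrt(max(df - 3, 1))
    fc_rows[[length(fc_rows) + 1L]] <- data.frame(
      region_i = ut[, 1L], region_j = ut[, 2L], scale = s,
      r = R[ut], z = z, df = df)
    wv <- wavelet_variance(d, scales = s)[1L, ]
    var_rows[[length(var_rows) + 1L]] <- data.frame(
      region = seq_along(wv), scale = s, variance = wv,
      log_variance = log(wv))
  }
  fc_path <- file.path(dir, paste0(prefix, "_fc.csv"))
  var_path <- file.path(dir, paste0(prefix, "_variance.csv"))
  utils::write.csv(do.call(rbind, fc_rows), fc_path, row.names = FALSE)
  utils::write.csv(do.call(rbind, var_rows), var_path, row.names = FALSE)
  invisible(c(fc = fc_path, variance = var_path))
}
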