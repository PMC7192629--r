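#' Read a sample manifest
#'
#' A manifest is a TSV with a header and columns `label`, `signal`
#' (bedgraph path) and optionally `control` (bedgraph path, empty for
#' none). Relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest path.
#' @return A data.frame with columns `label`, `signal`, `control`.
#' @export
read_manifest <- function(path) {
  mf <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, colClasses = "character")
  if (!all(c("label", "signal") %in% names(mf)))
    stop("manifest must have 'label' and 'signal' columns: ", path)
  if (is.null(mf$control)) mf$control <- ""
  mf$control[is.na(mf$control)] <- ""
  if (anyDuplicated(mf$label))
    stop("duplicate sample label in manifest: ",
         mf$label[duplicated(mf$label)][1L])
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(p == "" | grepl("^/", p), p,
                                file.path(base, p))
  mf$signal <- resolve(mf$signal)
  mf$control <- resolve(mf$control)
  for (i in seq_len(nrow(mf))) {
    if (!file.exists(mf$signal[i]))
      stop("manifest row '", mf$label[i], "': signal file not found: ",
           mf$signal[i])
    if (mf$control[i] != "" && !file.exists(mf$control[i]))
      stop("manifest row '", mf$label[i], "': control file not found: ",
           mf$control[i])
  }
  mf
}

#' Run the full normalization pipeline over a manifest
#'
#' Loads the binned tracks named in the manifest, normalizes them with
#' [normalize_set()] (or one of the baseline methods), and writes, per
#' sample: the normalized bedgraph, a -log10 p-value bedgraph of the
#' normalized signal under the dynamic NB background, a peak BED at `fdr`,
#' and a model JSON (alpha, beta, FRiP, NB parameters, region counts). A
#' `run_log.json` captures the package version, seed and every setting, so
#' a rerun with identical inputs reproduces the outputs byte for byte.
#'
#' @param manifest Path to a manifest TSV, or a data.frame as returned by
#'   [read_manifest()].
#' @param chrom_sizes Path to a chrom.sizes file, or a named vector /
#'   two-column data.frame of chromosome lengths.
#' @param out_dir Output directory (created if needed).
#' @param bin_size Bin width in bp (default 200).
#' @param fdr FDR threshold for region calling (default 0.1).
#' @param reference Reference mode for [select_reference()].
#' @param method `"s3norm"` (default), `"tsnorm"`, `"qtnorm"` or
#'   `"manorm"` (the simplified MA-plot baseline).
#' @param signal Passed to [normalize_set()] (`"counts"` or `"pvalue"`).
#' @param seed Recorded in the log; the pipeline itself is deterministic.
#' @return Invisibly, the [normalize_set()] result augmented with
#'   `out_dir` and `files`.
#' @export
run_pipeline <- function(manifest, chrom_sizes, out_dir, bin_size = 200L,
                         fdr = 0.1, reference = "max_frip",
                         method = c("s3norm", "tsnorm", "qtnorm", "manorm"),
                         signal = "counts", seed = NULL) {
  method <- match.arg(method)
  mf <- if (is.data.frame(manifest)) manifest else read_manifest(manifest)
  cs <- if (is.character(chrom_sizes) && length(chrom_sizes) == 1L)
    read_chrom_sizes(chrom_sizes) else chrom_sizes
  bins <- make_bins(cs, bin_size)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tracks <- lapply(seq_len(nrow(mf)), function(i)
    read_bedgraph(mf$signal[i], bins, label = mf$label[i]))
  controls <- lapply(seq_len(nrow(mf)), function(i)
    if (mf$control[i] == "") NULL
    else read_bedgraph(mf$control[i], bins, label = paste0(mf$label[i], ".ctrl")))
  if (all(vapply(controls, is.null, TRUE))) controls <- NULL

  res <- normalize_set(tracks, controls = controls, fdr = fdr,
                       reference = reference, signal = signal)
  if (method != "s3norm") {
    ref_track <- res$reference$track
    res$normalized <- lapply(seq_along(tracks), function(i) {
      if (!is.na(res$reference$index) && i == res$reference$index)
        return(tracks[[i]])
      switch(method,
             tsnorm = tsnorm(ref_track, tracks[[i]]),
             qtnorm = qtnorm(ref_track, tracks[[i]]),
             manorm = manorm_simplified(ref_track, tracks[[i]],
                                        res$regions$common_peak))
    })
    names(res$normalized) <- mf$label
  }

  files <- list()
  for (i in seq_len(nrow(mf))) {
    lab <- mf$label[i]
    norm_path <- file.path(out_dir, paste0(lab, ".", method, ".bedgraph"))
    write_bedgraph(res$normalized[[i]], norm_path)
    # p-value track of the normalized signal (continuous NB tail)
    bgfit <- res$nb_fits[[i]]
    pv_norm <- nb_pvalue_track(res$normalized[[i]], res$local_controls[[i]],
                               bgfit)
    pv_path <- file.path(out_dir, paste0(lab, ".nbp.bedgraph"))
    write_bedgraph(pv_norm, pv_path)
    bed_path <- file.path(out_dir, paste0(lab, ".peaks.bed"))
    write_peaks_bed(res$masks[[i]], bed_path)
    model <- res$models[[i]]
    json_path <- file.path(out_dir, paste0(lab, ".model.json"))
    jsonlite::write_json(list(
      label = lab, method = if (method == "manorm") "manorm-simplified" else method,
      alpha = model$alpha, beta = model$beta,
      constraint_residual = model$constraint_residual,
      iterations = model$iterations, solver = model$method,
      reference = model$reference_label,
      frip = unname(res$frip[i]),
      nb = list(p = bgfit$p, s = bgfit$s, p0 = bgfit$p0,
                m_ctrl = bgfit$m_ctrl),
      regions_used = as.list(model$regions_used)
    ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files[[lab]] <- c(normalized = norm_path, pvalues = pv_path,
                      peaks = bed_path, model = json_path)
  }

  jsonlite::write_json(list(
    package = "s3norm",
    version = as.character(utils::packageVersion("s3norm")),
    seed = seed, bin_size = bin_size, fdr = fdr,
    reference_mode = reference, method = method, signal = signal,
    samples = mf$label,
    reference_chosen = res$reference$track$label,
    n_common_peak_bins = sum(res$regions$common_peak$is_peak),
    n_common_background_bins = sum(res$regions$common_background$is_peak),
    alpha = lapply(res$models, `[[`, "alpha"),
    beta = lapply(res$models, `[[`, "beta"),
    frip = as.list(res$frip)
  ), file.path(out_dir, "run_log.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)

  res$out_dir <- out_dir
  res$files <- files
  invisible(res)
}
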