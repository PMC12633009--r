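#' @include fit.R
NULL

# FNV-1a hash of a string, hex-encoded; used to stamp output headers so a
# run can be matched to its configuration
.configHash <- function(x) {
  # 32-bit FNV-1a in split 16-bit words (doubles cannot hold the full
  # 32 x 24 bit product and bitwXor() is integer-only)
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 65536), as.integer(b %% 65536)) +
      65536 * bitwXor(as.integer(h %/% 65536), as.integer(b %/% 65536))
    h <- (h %% 65536 * 16777619 +
            (h %/% 65536 * 16777619) %% 65536 * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# metadata block written at the top of every artifact file
.metadataHeader <- function(config = list()) {
  cfg <- paste(sprintf("%s=%s", names(config),
                       vapply(config, function(v) paste(format(v), collapse = ","),
                              character(1))),
               collapse = " ")
  c(sprintf("# syntenyDecay %s",
            as.character(utils::packageVersion("syntenyDecay"))),
    sprintf("# config: %s", cfg),
    sprintf("# config_hash: %s", .configHash(cfg)))
}

#' Read a block-size table into empirical distributions
#'
#' Reads a tab-separated block size table with header columns `pair_id`,
#' `species_a`, `species_b`, `t_subs_per_site`, `block_size`, `count`
#' (leading `#` metadata lines are skipped) and builds one [EmpiricalPMF]
#' per `pair_id`. Duplicate `(pair_id, block_size)` rows have their counts
#' summed with a warning; malformed rows raise an error naming the line.
#'
#' @param path Path to the TSV file.
#' @param nMin Smallest block size retained (default 3).
#' @return Named list of [EmpiricalPMF]; attribute `"pairs"` holds a data
#'   frame of pair metadata (`pair_id`, `species_a`, `species_b`, `t_subs`).
#' @export
readBlockSizes <- function(path, nMin = 3L) {
  lines <- readLines(path)
  isMeta <- startsWith(lines, "#")
  dataLineNo <- which(!isMeta)
  df <- utils::read.delim(text = lines[!isMeta], stringsAsFactors = FALSE)
  required <- c("pair_id", "species_a", "species_b", "t_subs_per_site",
                "block_size", "count")
  if (!all(required %in% names(df)))
    stop("missing columns: ",
         paste(setdiff(required, names(df)), collapse = ", "))
  bad <- which(!is.finite(df$block_size) | df$block_size < 1 |
                 df$block_size != floor(df$block_size) |
                 !is.finite(df$count) | df$count < 1 |
                 !is.finite(df$t_subs_per_site) | df$t_subs_per_site < 0)
  if (length(bad))
    stop("malformed row at line ", dataLineNo[bad[1L] + 1L],
         " of ", path, " (block_size must be a positive integer, count >= 1,",
         " t_subs_per_site >= 0)")
  dup <- duplicated(df[c("pair_id", "block_size")])
  if (any(dup)) {
    warning("summed counts of ", sum(dup),
            " duplicate (pair_id, block_size) rows in ", path)
  }
  pairs <- unique(df[c("pair_id", "species_a", "species_b",
                       "t_subs_per_site")])
  if (anyDuplicated(pairs$pair_id))
    stop("pair_id with inconsistent species or t_subs_per_site in ", path)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    rows <- df[df$pair_id == pairs$pair_id[i], ]
    empiricalPmf(rows[c("block_size", "count")],
                 t = pairs$t_subs_per_site[i], nMin = nMin,
                 pairId = pairs$pair_id[i])
  })
  names(out) <- pairs$pair_id
  names(pairs)[names(pairs) == "t_subs_per_site"] <- "t_subs"
  attr(out, "pairs") <- pairs
  out
}

#' Write a block-size table
#'
#' Writes per-pair block size counts in the TSV layout read by
#' [readBlockSizes()], preceded by a `#` metadata block.
#'
#' @param table Data frame with columns `pair_id`, `species_a`, `species_b`,
#'   `t_subs_per_site`, `block_size`, `count`.
#' @param path Output path.
#' @param config Named list echoed into the metadata header.
#' @return `path`, invisibly.
#' @export
writeBlockSizes <- function(table, path, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.metadataHeader(config), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write ensemble simulation output
#'
#' `writeEnsembleReplicates()` writes the per-replicate block size counts
#' (`replicate`, `block_size`, `count`); `writeEnsembleSummary()` the
#' across-replicate summary (`block_size`, `mean_prob`, `sd_prob`). Both
#' start with a `#` metadata block.
#'
#' @param ensemble A [SimEnsemble].
#' @param path Output path.
#' @param config Named list echoed into the metadata header.
#' @return `path`, invisibly.
#' @export
writeEnsembleReplicates <- function(ensemble, path, config = list()) {
  rows <- do.call(rbind, lapply(seq_along(ensemble@replicateCounts),
    function(r) {
      counts <- ensemble@replicateCounts[[r]]
      data.frame(replicate = r, block_size = as.integer(names(counts)),
                 count = as.integer(counts))
    }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.metadataHeader(config), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEnsembleReplicates
#' @export
writeEnsembleSummary <- function(ensemble, path, config = list()) {
  rows <- data.frame(block_size = ensemble@support,
                     mean_prob = ensemble@mean, sd_prob = ensemble@sd)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.metadataHeader(config), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read fit results as JSON lines
#'
#' One JSON record per (pair, model) with the fitted parameters, divergence,
#' truncation window and, for the 2-cut and combined models, the
#' internal-consistency diagnostics. The first line is a JSON metadata
#' record (`{"_meta": ...}`).
#'
#' @param fits Either a list of [FitResult] or a named list of such lists
#'   (one per pair, as from [fitAllModels()] applied per pair).
#' @param path Output path.
#' @param config Named list echoed into the metadata record.
#' @return `writeFits()` returns `path` invisibly; `readFits()` a data
#'   frame with one row per record.
#' @export
writeFits <- function(fits, path, config = list()) {
  if (length(fits) && is(fits[[1L]], "FitResult")) fits <- list(pair = fits)
  con <- file(path, "w")
  on.exit(close(con))
  meta <- list(`_meta` = list(
    tool = "syntenyDecay",
    version = as.character(utils::packageVersion("syntenyDecay")),
    config = config))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), con)
  for (pair in names(fits)) {
    for (f in fits[[pair]]) {
      rec <- list(pair_id = pair, model = f@modelId,
                  params = as.list(modelParams(f@model)), kl = f@kl,
                  t_subs = f@t, n_min = f@nMin, n_max = f@nMax,
                  restarts_converged = f@restartsConverged,
                  best_start_index = f@bestStartIndex)
      if (f@modelId %in% c("two_cut", "combined")) {
        rec$eps_overlap <- overlapError(f@model, f@t)
        rec$eps_multicut <- multicutError(f@model, f@t)
      }
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' @rdname writeFits
#' @export
readFits <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON)
  recs <- recs[!vapply(recs, function(r) "_meta" %in% names(r), logical(1))]
  do.call(rbind, lapply(recs, function(r) {
    p <- r$params
    data.frame(
      pair_id = r$pair_id, model = r$model, kl = r$kl, t_subs = r$t_subs,
      n_min = r$n_min, n_max = r$n_max,
      kappa = if (!is.null(p$kappa)) p$kappa else NA_real_,
      gamma = if (!is.null(p$gamma)) p$gamma else NA_real_,
      theta = if (!is.null(p$theta)) p$theta else NA_real_,
      kappaH = if (!is.null(p$kappaH)) p$kappaH else NA_real_,
      kappaC = if (!is.null(p$kappaC)) p$kappaC else NA_real_,
      rHC = if (!is.null(p$rHC)) p$rHC else NA_real_,
      rCH = if (!is.null(p$rCH)) p$rCH else NA_real_,
      eps_overlap = if (!is.null(r$eps_overlap)) r$eps_overlap else NA_real_,
      eps_multicut = if (!is.null(r$eps_multicut)) r$eps_multicut
        else NA_real_,
      row.names = NULL)
  }))
}
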