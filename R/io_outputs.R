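#' Write pipeline results to a directory
#'
#' Accepts a named list of stage results and writes whatever is present:
#' `segments` as a `.hom`-dialect table, `hotspots` as BED plus a TSV with
#' frequency/threshold/empirical-P columns (plus the null distribution for
#' audit), `inbreeding`/`diversity`/`burden`/`windows`/`overlap` as TSVs,
#' and `pca` scores as TSV. The run `config` (with its seed) is echoed into
#' `manifest.json` together with the list of files written and stage
#' timings; a plain-text `run.log` records the same. Re-running with the
#' same inputs and seed reproduces byte-identical TSV/BED outputs.
#'
#' @param results named list; recognized names above, anything else that is
#'   a data.frame is written as `<name>.tsv`.
#' @param out_dir output directory (created if needed).
#' @param config optional named list echoed into the manifest.
#' @return the manifest, invisibly.
#' @export
write_outputs <- function(results, out_dir, config = NULL) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  probe <- file.path(out_dir, ".write_test")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("directory not writable: ", out_dir)
  unlink(probe)

  files <- character(0)
  timings <- list()
  logline <- character(0)
  stamp <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    logline <<- c(logline, paste0("stage ", name, ": ", timings[[name]], "s"))
  }
  add <- function(path) files <<- c(files, basename(path))
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    add(path)
  }

  if (!is.null(results$segments))
    stamp("segments", {
      path <- file.path(out_dir, "roh.hom")
      write_segments(results$segments, path, "hom")
      add(path)
    })
  if (!is.null(results$hotspots)) {
    stamp("hotspots", {
      hr <- results$hotspots
      bed <- file.path(out_dir, "hotspots.bed")
      con <- file(bed, "w")
      writeLines("#chrom\tstart\tend\tpeak_freq\tmin_p", con)
      if (nrow(hr$hotspots))
        writeLines(paste(hr$hotspots$chrom, format_bp(hr$hotspots$start),
                         format_bp(hr$hotspots$end),
                         hr$hotspots$peak_freq, hr$hotspots$min_p,
                         sep = "\t"), con)
      close(con)
      add(bed)
      snp <- hr$snp_table
      snp$threshold <- hr$threshold_freq
      tsv(snp, "hotspot_snps.tsv")
      tsv(data.frame(max_freq = hr$null_max_freq %||% NA_real_),
          "null_max.tsv")
    })
  }
  for (name in c("inbreeding", "diversity", "burden", "windows", "overlap"))
    if (!is.null(results[[name]]) && is.data.frame(results[[name]]))
      stamp(name, tsv(results[[name]], paste0(name, ".tsv")))
  if (!is.null(results$pca))
    stamp("pca", tsv(data.frame(sample_id = rownames(results$pca$scores),
                                results$pca$scores,
                                check.names = FALSE), "pca_scores.tsv"))
  extra <- setdiff(names(results),
                   c("segments", "hotspots", "inbreeding", "diversity",
                     "burden", "windows", "overlap", "pca"))
  for (name in extra)
    if (is.data.frame(results[[name]]))
      stamp(name, tsv(results[[name]], paste0(name, ".tsv")))

  manifest <- list(package = "rohscan",
                   version = as.character(utils::packageVersion("rohscan")),
                   config = config, files = files, timings = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  writeLines(c(paste0("rohscan run, seed=",
                      if (!is.null(config$seed)) config$seed else "NA"),
               logline,
               paste0("config: ", jsonlite::toJSON(config, auto_unbox = TRUE,
                                                   null = "null"))),
             file.path(out_dir, "run.log"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
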