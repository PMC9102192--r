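#' Write a force curve as two-column tab-separated text
#'
#' Format: "#"-prefixed metadata header lines (`# key: value`), then a
#' header row `height_um	force_nN` and one sample per line.
#'
#' @param curve A [force_curve()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(curve$meta))
    writeLines(sprintf("# %s: %s", k, format(curve$meta[[k]])), con)
  writeLines("height_um\tforce_nN", con)
  utils::write.table(
    data.frame(h = formatC(curve$height, format = "g", digits = 15),
               f = formatC(curve$force, format = "g", digits = 15)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a force curve from two-column tab-separated text
#'
#' @param path File written by [write_force_curve()] (metadata lines
#'   prefixed with "#", then `height_um`/`force_nN` columns).
#' @return A [force_curve()] with metadata restored as character values.
#' @export
read_force_curve <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    k <- sub(":.*$", "", kv)
    v <- trimws(sub("^[^:]*:", "", kv))
    meta[[trimws(k)]] <- v
  }
  body <- lines[!grepl("^#", lines)]
  d <- utils::read.table(text = body, header = TRUE, sep = "\t")
  force_curve(d$height_um, d$force_nN, meta = meta)
}

#' Write an RGB image array as 8-bit PNG
#'
#' @param image H x W x 3 numeric array with values 0-255.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' Read an 8-bit PNG into a 0-255 array
#'
#' @param path PNG file. RGB images return H x W x 3 arrays; single-channel
#'   masks return a matrix.
#' @return Numeric array/matrix with values 0-255.
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  round(x * 255)
}

#' Generate and write a complete synthetic study to disk
#'
#' Runs every generator and writes the file set the pipeline consumes:
#' `cohort.csv` (markers, covariates, clinical factors, lactate panel),
#' `survival.csv`, `qpcr.csv`, `rtdc_events.csv` (headered UTF-8 CSV,
#' "." decimal), the reference/plate images as 8-bit RGB PNG, the ROI as a
#' single-channel PNG mask (255 = inside), force curves as two-column
#' tab-separated text, and `truth.json` with every planted ground-truth
#' record.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the list of generated objects (`cohort`, `colony`,
#'   `afm`, `rtdc`, `qpcr`).
#' @export
simulate_study <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)

  cohort <- gen_cohort(config)
  colony <- gen_colony_images(config)
  afm <- gen_force_curves(config)
  rtdc <- gen_rtdc_events(config)
  qpcr <- gen_qpcr(config)

  wcsv <- function(d, f) utils::write.csv(d, p(f), row.names = FALSE,
                                          fileEncoding = "UTF-8")
  wcsv(cohort$cohort[setdiff(names(cohort$cohort), c("time", "event"))],
       "cohort.csv")
  wcsv(cohort$cohort[c("id", "time", "event")], "survival.csv")
  wcsv(qpcr$records, "qpcr.csv")
  wcsv(rtdc$events, "rtdc_events.csv")

  write_image_png(colony$reference, p("reference.png"))
  png::writePNG(ifelse(colony$roi, 1, 0), target = p("roi.png"))
  for (i in seq_along(colony$images))
    write_image_png(colony$images[[i]], p(sprintf("img%02d.png", i)))

  dir.create(p("curves"), showWarnings = FALSE)
  for (i in seq_along(afm$curves))
    write_force_curve(afm$curves[[i]], p("curves", sprintf("c%04d.txt", i)))

  truth <- list(cohort = cohort$truth, colony = colony$truth,
                afm = afm$truth, rtdc = rtdc$truth, qpcr = qpcr$truth)
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns",
                       digits = NA, auto_unbox = TRUE)
  invisible(list(cohort = cohort, colony = colony, afm = afm, rtdc = rtdc,
                 qpcr = qpcr))
}
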