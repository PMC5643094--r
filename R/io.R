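#' Read and write track CSV files
#'
#' The single track exchange format: a comma-separated, dot-decimal, UTF-8
#' CSV with mandatory header \code{track_id,kind,frame,t_s,x_um,y_um} and
#' one row per track point.  \code{read_tracks} validates the table: all
#' columns present and numeric where required, frames unique and time
#' strictly increasing within each track.
#'
#' @param path file path.
#' @return \code{read_tracks}: a validated track \code{data.frame};
#'   \code{write_tracks}: \code{path}, invisibly.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(track_id = "character"))
  need <- c("track_id", "kind", "frame", "t_s", "x_um", "y_um")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("track CSV missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("frame", "t_s", "x_um", "y_um")) {
    if (!is.numeric(tab[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[col]]))))[1]
      stop(sprintf("non-numeric value in column '%s' at data row %d",
                   col, bad))
    }
  }
  if (anyNA(tab[need]))
    stop("track CSV contains missing values at data row ",
         which(!stats::complete.cases(tab[need]))[1])
  for (tr in split(tab, tab$track_id)) {
    if (anyDuplicated(tr$frame))
      stop("duplicated frame in track '", tr$track_id[1], "'")
    if (is.unsorted(tr$t_s, strictly = TRUE))
      stop("non-monotone time in track '", tr$track_id[1], "'")
  }
  tab
}

#' @rdname read_tracks
#' @param tracks a track table.
#' @export
write_tracks <- function(tracks, path) {
  .check_track_table(tracks)
  utils::write.csv(tracks[, c("track_id", "kind", "frame", "t_s",
                              "x_um", "y_um")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages of the workflow in order - synthetic track
#' generation (or loading), track analytics, the cortical dwell procedure,
#' and optionally the static-rod transport simulation - writing summary
#' tables, dwell events, fit reports, figures and a run manifest into
#' \code{out_dir}.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{geometry}{an \code{oocyte_geometry} or a geometry JSON path
#'       (default: \code{ellipse_geometry()}).}
#'     \item{tracks}{a track table or track CSV path; when absent, the
#'       synth stage generates EB1 and oskar tracks.}
#'     \item{eb1, oskar}{parameter objects for the synth stage (defaults
#'       \code{eb1_params()}, \code{oskar_params()}).}
#'     \item{simulate}{logical: run the static-rod simulation
#'       (default FALSE).}
#'     \item{sim}{a \code{static_rod_config} for the simulation stage.}
#'   }
#' @param out_dir output directory (created if needed).
#' @param seed integer seed governing all stochastic stages.
#' @return (invisibly) a list with the main results: \code{track_stats},
#'   \code{summary}, \code{dwell_events}, \code{dwell_comparison},
#'   \code{sim} (or NULL), \code{manifest}.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- config$geometry
  if (is.null(geom)) geom <- ellipse_geometry()
  if (is.character(geom)) {
    if (!file.exists(geom)) stop("geometry stage: file not found: ", geom)
    geom <- read_geometry(geom)
  }
  stopifnot(inherits(geom, "oocyte_geometry"))

  ## stage: synth or input
  if (!is.null(config$tracks)) {
    tracks <- if (is.character(config$tracks)) read_tracks(config$tracks)
              else config$tracks
  } else {
    ep <- if (is.null(config$eb1)) eb1_params() else config$eb1
    op <- if (is.null(config$oskar)) oskar_params() else config$oskar
    tracks <- rbind(generate_eb1_tracks(ep, geom, seed = seed),
                    generate_oskar_tracks(op, geom, seed = seed + 1L))
    write_tracks(tracks, file.path(out_dir, "tracks.csv"))
  }

  ## stage: analytics
  st <- track_stats(tracks, geom)
  utils::write.csv(st, file.path(out_dir, "track_stats.csv"),
                   row.names = FALSE)
  osk <- st[st$kind == "oskar", , drop = FALSE]
  eb <- st[st$kind == "eb1", , drop = FALSE]
  freq <- distance_binned_frequency(if (nrow(osk)) osk else st)
  utils::write.csv(freq, file.path(out_dir, "distance_frequency.csv"),
                   row.names = FALSE)
  dirhist <- direction_histogram(if (nrow(osk)) osk else st)
  utils::write.csv(cbind(bin_deg = rownames(dirhist), as.data.frame(dirhist)),
                   file.path(out_dir, "direction_histogram.csv"),
                   row.names = FALSE)
  if (nrow(eb)) {
    spd <- speed_by_region(eb)
    utils::write.csv(spd, file.path(out_dir, "speed_by_region.csv"),
                     row.names = FALSE)
  }
  grDevices::png(file.path(out_dir, "rose_plot.png"), width = 640,
                 height = 640)
  plot_direction_rose(dirhist)
  grDevices::dev.off()

  ## stage: dwell
  events <- select_cortex_tracks(
    tracks[tracks$kind == "eb1", , drop = FALSE], geom)
  utils::write.csv(events, file.path(out_dir, "dwell_events.csv"),
                   row.names = FALSE)
  cmp <- NULL
  post <- events[events$cortex_region == "posterior", , drop = FALSE]
  lat <- events[events$cortex_region == "lateral", , drop = FALSE]
  if (nrow(post) >= 3L && nrow(lat) >= 3L) {
    cmp <- compare_regions(post, lat)
    rep <- list(n = as.list(cmp$n), mean = as.list(cmp$mean),
                max = as.list(cmp$max), rank_sum_p = cmp$rank_sum_p)
    if (!is.null(cmp$fit_posterior))
      rep$fit_posterior <- as.list(coef(cmp$fit_posterior))
    if (!is.null(cmp$fit_lateral))
      rep$fit_lateral <- as.list(coef(cmp$fit_lateral))
    jsonlite::write_json(rep, file.path(out_dir, "dwell_fits.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  ## stage: simulation (optional)
  sim <- NULL
  if (isTRUE(config$simulate)) {
    sc <- if (is.null(config$sim)) static_rod_config() else config$sim
    rods <- sample_static_rods(sc, geom, seed = seed + 2L)
    sim <- run_cargo_transport(rods, sc, geom, seed = seed + 3L)
    utils::write.csv(sim$density$counts,
                     file.path(out_dir, "cargo_density.csv"),
                     row.names = FALSE)
  }

  manifest <- list(command = "run_pipeline",
                   seed = as.integer(seed),
                   stages = c("synth/input", "analytics", "dwell",
                              if (isTRUE(config$simulate)) "sim"),
                   n_tracks = length(unique(tracks$track_id)),
                   package_version =
                     as.character(utils::packageVersion("oocytemt")),
                   started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(track_stats = st,
                 summary = list(distance_frequency = freq,
                                direction_histogram = dirhist),
                 dwell_events = events, dwell_comparison = cmp,
                 sim = sim, manifest = manifest))
}
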