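#' Write a synthetic cohort to disk
#'
#' Renders every frame of every video to 8-bit RGB PNG (one directory per
#' video, zero-padded frame filenames), writes the per-video sidecar JSON,
#' the cohort roster CSV and a manifest recording the seed and profiles.
#'
#' @param cohort As returned by [generate_cohort()].
#' @param dir Output directory.
#' @param seed The master seed used to generate the cohort (recorded in the
#'   manifest).
#' @param noise_sd Grey-level noise SD passed to the renderer.
#' @return Invisibly, the cohort directory.
#' @export
write_cohort <- function(cohort, dir, seed = NA, noise_sd = 8) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (v in cohort$videos) {
    vdir <- file.path(dir, v$video_id)
    dir.create(vdir, showWarnings = FALSE)
    for (i in seq_len(nrow(v$frames))) {
      fr <- render_video_frame(v, i, noise_sd = noise_sd)
      png::writePNG(fr$img / 255,
                    file.path(vdir, sprintf("frame_%05d.png",
                                            v$frames$frame_index[i])))
    }
    jsonlite::write_json(video_sidecar(v), file.path(vdir, "sidecar.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(cohort$roster, file.path(dir, "roster.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(seed = seed, n_videos = length(cohort$videos),
                            video_ids = names(cohort$videos)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

read_sidecar <- function(vdir) {
  path <- file.path(vdir, "sidecar.json")
  if (!file.exists(path)) stop("missing sidecar.json in ", vdir)
  sc <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_sidecar(sc)
  sc
}

#' Score one video directory
#'
#' Reads the PNG frames and sidecar of one video directory, scores every
#' frame with both per-frame scorers and writes `frame_scores.csv`
#' (`frame_index`, `contrast`, `bubble_class`, `rg_ratio`,
#' `cleanliness_class`) into the directory. Already-scored videos are
#' skipped unless `overwrite`, so a cohort run is resumable.
#'
#' @param vdir Video directory containing `frame_*.png` and `sidecar.json`.
#' @param params GLCM parameters.
#' @param tau Calibrated contrast threshold.
#' @param rg_threshold Cleanliness cut-off.
#' @param overwrite Re-score even if `frame_scores.csv` exists.
#' @return The per-frame scores data.frame.
#' @export
score_video_dir <- function(vdir, params = glcm_params(), tau,
                            rg_threshold = 1.6, overwrite = FALSE) {
  out_path <- file.path(vdir, "frame_scores.csv")
  if (file.exists(out_path) && !overwrite)
    return(utils::read.csv(out_path, stringsAsFactors = FALSE))
  sc <- read_sidecar(vdir)
  files <- sort(list.files(vdir, pattern = "^frame_\\d+\\.png$"))
  if (!length(files)) stop("no frames found in ", vdir)
  mask <- fov_mask(sc$width, sc$height, sc$fov_radius_frac)
  rows <- lapply(files, function(f) {
    img <- png::readPNG(file.path(vdir, f)) * 255
    fr <- new_frame(img, mask)
    cbind(frame_index = as.integer(sub("frame_(\\d+)\\.png", "\\1", f)),
          score_frame(fr, params, tau, rg_threshold))
  })
  scores <- do.call(rbind, rows)
  utils::write.csv(scores, out_path, row.names = FALSE)
  scores
}

#' Score a cohort directory
#'
#' Applies [score_video_dir()] to every video directory under `dir` and
#' writes the per-video summary table `video_summaries.csv`.
#'
#' @param dir Cohort directory (as written by [write_cohort()]).
#' @inheritParams score_video_dir
#' @return The per-video summary data.frame.
#' @export
score_cohort <- function(dir, params = glcm_params(), tau, rg_threshold = 1.6,
                         overwrite = FALSE) {
  vdirs <- list.dirs(dir, recursive = FALSE)
  vdirs <- vdirs[file.exists(file.path(vdirs, "sidecar.json"))]
  if (!length(vdirs)) stop("no video directories found in ", dir)
  summaries <- do.call(rbind, lapply(vdirs, function(vd) {
    scores <- score_video_dir(vd, params, tau, rg_threshold, overwrite)
    summarize_video(scores, read_sidecar(vd))
  }))
  utils::write.csv(summaries, file.path(dir, "video_summaries.csv"),
                   row.names = FALSE)
  summaries
}

#' Score a synthetic video in memory
#'
#' Renders and scores every frame of a `ce_video` without touching disk —
#' the fast path used by the acceptance pipeline and the analysis scripts.
#'
#' @param video A `ce_video`.
#' @param params GLCM parameters.
#' @param tau Calibrated contrast threshold.
#' @param rg_threshold Cleanliness cut-off.
#' @param noise_sd Grey-level noise SD for rendering.
#' @param sb_only Score only the small-bowel frames (gastric/colonic frames
#'   get `NA` scores but keep their rows).
#' @return Per-frame scores data.frame (same layout as [score_video_dir()]).
#' @export
score_video <- function(video, params = glcm_params(), tau, rg_threshold = 1.6,
                        noise_sd = 8, sb_only = FALSE) {
  n <- nrow(video$frames)
  idx <- seq_len(n)
  if (sb_only) idx <- idx[video$frames$segment == "sb"]
  contrast <- rep(NA_real_, n); rg <- rep(NA_real_, n)
  for (i in idx) {
    fr <- render_video_frame(video, i, noise_sd = noise_sd)
    contrast[i] <- frame_contrast(fr, params)
    rg[i] <- rg_ratio(fr)
  }
  data.frame(frame_index = video$frames$frame_index,
             contrast = contrast,
             bubble_class = ifelse(is.na(contrast), NA,
                                   ifelse(contrast >= tau, "abundant", "scarce")),
             rg_ratio = rg,
             cleanliness_class = ifelse(is.na(rg), NA,
                                        ifelse(rg > rg_threshold, "adequate",
                                               "inadequate")),
             stringsAsFactors = FALSE)
}
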