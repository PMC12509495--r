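SESSION_SCHEMA_VERSION <- 1L

#' Write a session to a directory
#'
#' Serializes a synthetic or recorded session as plain-text files:
#' `photometry.csv` (t, f465, f405), `pose.csv` (frame, neck/nose x-y),
#' `ethogram.csv` (frame + one 0/1 column per behavior), `objects.json`,
#' `meta.json` (rates, identifiers, schema version) and, for synthetic
#' sessions, `truth.csv` with the latent components.
#'
#' @param session a `synth_session` (or a list with the same fields).
#' @param dir output directory; must exist unless `create = TRUE`.
#' @param create create the directory (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, create = TRUE) {
  if (!dir.exists(dir)) {
    if (!create) stop("directory does not exist: ", dir, call. = FALSE)
    dir.create(dir, recursive = TRUE)
  }
  if (!is.null(session$photometry)) {
    ph <- session$photometry
    data.table::fwrite(data.table::data.table(t = ph$t, f465 = ph$f465,
                                              f405 = ph$f405),
                       file.path(dir, "photometry.csv"))
  }
  traj <- session$trajectory
  data.table::fwrite(
    data.table::data.table(frame = traj$frame, neck_x = traj$neck_x,
                           neck_y = traj$neck_y, nose_x = traj$nose_x,
                           nose_y = traj$nose_y),
    file.path(dir, "pose.csv"))
  data.table::fwrite(as.data.frame(session$ethogram),
                     file.path(dir, "ethogram.csv"))
  jsonlite::write_json(session$objects, file.path(dir, "objects.json"),
                       auto_unbox = TRUE, digits = NA)
  meta <- session$meta
  meta$schema_version <- SESSION_SCHEMA_VERSION
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(session$truth)) {
    tr <- session$truth
    dt <- data.table::data.table(t = tr$t, z_true = tr$z_true)
    for (nm in names(tr$components)) dt[[paste0("c_", nm)]] <- tr$components[[nm]]
    data.table::fwrite(dt, file.path(dir, "truth.csv"))
  }
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir session directory.
#' @return a list mirroring the written session: `photometry` (when
#'   present), `trajectory`, `ethogram`, `objects`, `truth` (when present)
#'   and `meta`.
#' @export
read_session <- function(dir) {
  if (!dir.exists(dir)) stop("no such session directory: ", dir, call. = FALSE)
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("meta.json missing in ", dir, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$schema_version) ||
      meta$schema_version != SESSION_SCHEMA_VERSION) {
    stop("unsupported session schema version in ", dir, call. = FALSE)
  }
  out <- list(meta = meta)
  pc <- file.path(dir, "photometry.csv")
  if (file.exists(pc)) {
    ph <- data.table::fread(pc)
    out$photometry <- structure(
      list(f465 = ph$f465, f405 = ph$f405, t = ph$t,
           rate = meta$photometry_rate, meta = meta),
      class = "photometry_session")
  }
  pose <- as.data.frame(data.table::fread(file.path(dir, "pose.csv")))
  pose$t <- pose$frame / meta$video_rate
  pose$speed <- compute_speed(pose, meta$video_rate)
  class(pose) <- c("trajectory", "data.frame")
  out$trajectory <- pose
  etho <- as.data.frame(data.table::fread(file.path(dir, "ethogram.csv")))
  class(etho) <- c("ethogram", "data.frame")
  out$ethogram <- etho
  out$objects <- lapply(jsonlite::read_json(file.path(dir, "objects.json"),
                                            simplifyVector = TRUE), as.numeric)
  tc <- file.path(dir, "truth.csv")
  if (file.exists(tc)) {
    tr <- data.table::fread(tc)
    comp_cols <- grep("^c_", names(tr), value = TRUE)
    out$truth <- structure(
      list(z_true = tr$z_true, t = tr$t, rate = meta$video_rate,
           components = setNames(lapply(comp_cols, function(cc) tr[[cc]]),
                                 sub("^c_", "", comp_cols))),
      class = "ground_truth")
  }
  out
}
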