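## ---- TSV serialization with commented key=value metadata headers --------

write_meta_header <- function(con, meta) {
  for (k in names(meta))
    writeLines(sprintf("# %s=%s", k, format(meta[[k]], digits = 15)), con)
}

read_meta_header <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# *[^ =]+=", lines, value = TRUE)
  kv <- sub("^# *", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

#' Write a work profile set to TSV
#'
#' Columns: the restraint-center grid, then one accumulated-work column
#' per trajectory. Protocol and seed metadata go into a commented
#' `key=value` header.
#'
#' @param ws a `work_profile_set`.
#' @param path output file.
#' @export
write_workset_tsv <- function(ws, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_meta_header(con, list(
    kind = "work_profile_set", base_seed = ws$base_seed,
    n_traj = ncol(ws$works), spring_k = ws$protocol$spring_k,
    speed = ws$protocol$speed, lambda_start = ws$protocol$lambda_start,
    lambda_end = ws$protocol$lambda_end, segment = ws$protocol$segment,
    temperature = ws$thermo$temperature, friction = ws$thermo$friction,
    timestep = ws$thermo$timestep))
  df <- data.frame(lambda = ws$lambda, ws$works)
  names(df) <- c("lambda", sprintf("W%03d", seq_len(ncol(ws$works))))
  utils::write.table(format(df, digits = 10, trim = TRUE), con,
                     sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read a work profile set from TSV
#'
#' Accepts files produced by [write_workset_tsv()] or any TSV whose first
#' column is the coordinate grid and remaining columns are per-trajectory
#' works; metadata in `# key=value` lines. Missing protocol metadata falls
#' back to the standard defaults with a warning.
#'
#' @param path input file.
#' @param thermo optional [thermo_settings()] overriding file metadata.
#' @return A `work_profile_set`.
#' @export
read_workset_tsv <- function(path, thermo = NULL) {
  meta <- read_meta_header(path)
  df <- utils::read.delim(path, comment.char = "#")
  num <- function(key, default) {
    if (!is.null(meta[[key]])) as.numeric(meta[[key]]) else {
      warning("missing metadata '", key, "', using default ", default)
      default
    }
  }
  if (is.null(thermo))
    thermo <- thermo_settings(temperature = num("temperature", 300),
                              friction = num("friction", 800),
                              timestep = num("timestep", 0.2))
  protocol <- steering_protocol(
    spring_k = num("spring_k", 150), speed = num("speed", 0.25),
    lambda_start = num("lambda_start", df[1, 1]),
    lambda_end = num("lambda_end", df[nrow(df), 1]),
    segment = meta$segment %||% "unknown")
  structure(
    list(lambda = df[[1]], works = as.matrix(df[, -1, drop = FALSE]),
         protocol = protocol, thermo = thermo,
         base_seed = as.numeric(meta$base_seed %||% NA)),
    class = "work_profile_set")
}

#' Write a free energy profile to TSV
#'
#' Columns: coordinate, `dG`, `uncertainty` (`sqrt(mse)`).
#'
#' @param fep a [free_energy_profile()].
#' @param path output file.
#' @export
write_profile_tsv <- function(fep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_meta_header(con, list(kind = "free_energy_profile",
                              provenance = fep$provenance, n = fep$n,
                              coord_name = fep$coord_name))
  df <- data.frame(coord = fep$coord, dG = fep$dG,
                   uncertainty = sqrt(fep$mse))
  utils::write.table(format(df, digits = 10, trim = TRUE), con,
                     sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read a free energy profile from TSV
#'
#' @param path input file (as written by [write_profile_tsv()]).
#' @return A [free_energy_profile()].
#' @export
read_profile_tsv <- function(path) {
  meta <- read_meta_header(path)
  df <- utils::read.delim(path, comment.char = "#")
  free_energy_profile(df$coord, df$dG, mse = df$uncertainty^2,
                      n = as.integer(meta$n %||% NA),
                      provenance = meta$provenance %||% "unknown",
                      coord_name = meta$coord_name %||% "coordinate")
}

#' Write umbrella-window samples to TSV
#'
#' Long format: one sample per line with its window index; window centers
#' and force constants in the metadata header.
#'
#' @param uset an `umbrella_set`.
#' @param path output file.
#' @export
write_umbrella_tsv <- function(uset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  centers <- vapply(uset$windows, `[[`, numeric(1), "center")
  kumb <- vapply(uset$windows, `[[`, numeric(1), "k_umb")
  write_meta_header(con, list(
    kind = "umbrella_set", base_seed = uset$base_seed,
    coord_name = uset$coord_name,
    centers = paste(centers, collapse = ","),
    k_umb = paste(kumb, collapse = ","),
    temperature = uset$thermo$temperature))
  df <- do.call(rbind, lapply(seq_along(uset$windows), function(i)
    data.frame(window = i, sample = uset$windows[[i]]$samples)))
  utils::write.table(format(df, digits = 10, trim = TRUE), con,
                     sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read umbrella-window samples from TSV
#'
#' @param path input file (as written by [write_umbrella_tsv()]).
#' @param thermo optional [thermo_settings()] overriding file metadata.
#' @return An `umbrella_set`.
#' @export
read_umbrella_tsv <- function(path, thermo = NULL) {
  meta <- read_meta_header(path)
  df <- utils::read.delim(path, comment.char = "#")
  centers <- as.numeric(strsplit(meta$centers, ",")[[1]])
  kumb <- as.numeric(strsplit(meta$k_umb, ",")[[1]])
  if (is.null(thermo))
    thermo <- thermo_settings(
      temperature = as.numeric(meta$temperature %||% 300),
      friction = 0.05, timestep = 0.2)
  wins <- lapply(seq_along(centers), function(i)
    list(center = centers[i], k_umb = kumb[i],
         samples = df$sample[df$window == i]))
  uset <- structure(
    list(windows = wins, thermo = thermo,
         coord_name = meta$coord_name %||% "dihedral (deg)",
         base_seed = as.numeric(meta$base_seed %||% NA)),
    class = "umbrella_set")
  uset$overlap_ok <- check_window_overlap(uset)
  uset
}
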