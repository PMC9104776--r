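guess_mass <- function(name) {
  el <- toupper(substr(gsub("^[0-9]+", "", name), 1L, 1L))
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
         P = 30.974)
  out <- unname(m[el])
  out[is.na(out)] <- 12.011
  out
}

#' Read a GRO structure file
#'
#' Fixed-column GROMACS GRO dialect (positions in nm, 3 decimals;
#' orthorhombic box on the last line). GRO carries no masses, so they
#' are inferred from the leading element letter of each atom name
#' unless supplied.
#'
#' @param path file path.
#' @param masses optional explicit atom masses (amu).
#' @return An [atom_frame()]; velocities, when present in the file, are
#'   attached as attribute `"velocities"`.
#' @export
read_gro <- function(path, masses = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("not a GRO file: fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(n)) stop("malformed GRO line 2: expected atom count")
  if (length(lines) < n + 3L)
    stop(sprintf("GRO file truncated: expected %d atom records", n))
  at <- lines[3:(n + 2L)]
  num <- function(s) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v))) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("malformed GRO atom record at line %d", bad + 2L))
    }
    v
  }
  pos <- cbind(num(substr(at, 21, 28)), num(substr(at, 29, 36)),
               num(substr(at, 37, 44)))
  names <- trimws(substr(at, 11, 15))
  has_vel <- all(nchar(at) >= 68)
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3L]),
                                              "\\s+")[[1L]]))
  if (length(box) < 3L || any(is.na(box[1:3])))
    stop(sprintf("malformed GRO box line at line %d", n + 3L))
  if (is.null(masses)) masses <- guess_mass(names)
  fr <- atom_frame(pos, masses, names, box[1:3])
  if (has_vel)
    attr(fr, "velocities") <- cbind(num(substr(at, 45, 52)),
                                    num(substr(at, 53, 60)),
                                    num(substr(at, 61, 68)))
  fr
}

#' Write a GRO structure file
#'
#' @param frame an [atom_frame()] or [cg_frame()] (bead types become
#'   residue and atom names).
#' @param path output path.
#' @param velocities optional N x 3 matrix (nm/ps).
#' @param title header line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(frame, path, velocities = NULL,
                      title = "written by ibicg") {
  if (inherits(frame, "cg_frame")) {
    names <- frame$types
    res <- frame$types
  } else {
    names <- frame$labels
    res <- rep("MOL", length(frame$labels))
  }
  n <- nrow(frame$positions)
  if (is.null(velocities)) velocities <- attr(frame, "velocities")
  lines <- character(n)
  for (i in seq_len(n)) {
    rec <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", i %% 100000L,
                   substr(res[i], 1, 5), substr(names[i], 1, 5),
                   i %% 100000L, frame$positions[i, 1],
                   frame$positions[i, 2], frame$positions[i, 3])
    if (!is.null(velocities))
      rec <- paste0(rec, sprintf("%8.4f%8.4f%8.4f", velocities[i, 1],
                                 velocities[i, 2], velocities[i, 3]))
    lines[i] <- rec
  }
  writeLines(c(title, sprintf("%5d", n), lines,
               sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2],
                       frame$box[3])), path)
  invisible(path)
}

#' Write a CG trajectory as multi-frame GRO text
#'
#' Frames are concatenated GRO blocks (title, atom count, records, box),
#' the plain-text trajectory dialect used throughout the package.
#'
#' @param traj a [cg_traj()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_traj <- function(traj, path) {
  stopifnot(inherits(traj, "cg_traj"))
  nf <- dim(traj$coords)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    fr <- cg_frame(traj$coords[f, , , drop = TRUE],
                   if (is.null(traj$masses)) rep(1, dim(traj$coords)[2])
                   else traj$masses, traj$types, traj$box)
    n <- nrow(fr$positions)
    writeLines(c(sprintf("frame %d", f), sprintf("%5d", n),
                 sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         seq_len(n) %% 100000L, substr(fr$types, 1, 5),
                         substr(fr$types, 1, 5), seq_len(n) %% 100000L,
                         fr$positions[, 1], fr$positions[, 2],
                         fr$positions[, 3]),
                 sprintf("%10.5f%10.5f%10.5f", fr$box[1], fr$box[2],
                         fr$box[3])), con)
  }
  invisible(path)
}

#' Read a multi-frame GRO trajectory
#'
#' @param path file path.
#' @param masses optional bead masses.
#' @return A [cg_traj()]; bead types from the atom-name column.
#' @export
read_traj <- function(path, masses = NULL) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i + 2L <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) stop(sprintf("malformed frame header at line %d", i + 1L))
    if (i + n + 2L > length(lines)) stop("trajectory truncated")
    at <- lines[(i + 2L):(i + n + 1L)]
    pos <- cbind(as.numeric(substr(at, 21, 28)),
                 as.numeric(substr(at, 29, 36)),
                 as.numeric(substr(at, 37, 44)))
    types <- trimws(substr(at, 11, 15))
    box <- as.numeric(strsplit(trimws(lines[i + n + 2L]), "\\s+")[[1L]])[1:3]
    frames[[length(frames) + 1L]] <-
      cg_frame(pos, if (is.null(masses)) rep(1, n) else masses, types, box)
    i <- i + n + 3L
  }
  if (length(frames) == 0L) stop("no frames found")
  cg_traj(frames)
}

#' Write a tabulated function or potential table
#'
#' Whitespace-delimited text with `#`-prefixed header lines carrying
#' kind, grid and units. Distributions are written as two columns
#' (x, value); potentials as three GROMACS-style columns (r, U, F) with
#' F = -U'. No Jacobian correction is ever folded into distribution
#' tables (recorded in the header so files are self-describing).
#'
#' @param f a [tab_fn()] or [potential_table()].
#' @param path output path.
#' @param provenance optional free-text provenance string.
#' @return `path`, invisibly.
#' @export
write_table <- function(f, path, provenance = NULL) {
  is_pot <- inherits(f, "potential_table")
  hdr <- c("# ibicg table",
           sprintf("# kind: %s", f$kind),
           sprintf("# x0: %.12g", f$x0),
           sprintf("# dx: %.12g", f$dx),
           sprintf("# n: %d", length(if (is_pot) f$U else f$values)),
           "# units: nm kJ/mol (angles: degrees)",
           "# jacobian_correction: none")
  if (is_pot)
    hdr <- c(hdr, sprintf("# r_cut: %.12g", f$r_cut),
             sprintf("# r_core: %.12g", f$r_core))
  if (!is.null(provenance)) hdr <- c(hdr, sprintf("# provenance: %s", provenance))
  x <- tab_grid(f)
  body <- if (is_pot)
    sprintf("%.10g %.12g %.12g", x, f$U, f$F)
  else sprintf("%.10g %.12g", x, f$values)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a tabulated function or potential table
#'
#' Inverse of [write_table()]; the round trip is lossless at the
#' written precision. Files missing a required header key are rejected
#' naming that key; a potential file whose force column disagrees with
#' the central-difference derivative of its U column is rejected.
#'
#' @param path file path.
#' @return A [tab_fn()] or [potential_table()] according to the header.
#' @export
read_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, required = TRUE) {
    pat <- sprintf("^#\\s*%s:\\s*", key)
    hit <- grep(pat, hdr, value = TRUE)
    if (length(hit) == 0L) {
      if (required) stop(sprintf("table header missing key '%s'", key))
      return(NULL)
    }
    sub(pat, "", hit[1L])
  }
  num <- function(s) if (s %in% c("NA", "none")) NA_real_ else as.numeric(s)
  kind <- get("kind")
  x0 <- num(get("x0"))
  dx <- num(get("dx"))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  vals <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  if (kind == "potential") {
    r_cut <- num(get("r_cut"))
    r_core <- num(get("r_core"))
    if (ncol(vals) < 3L) stop("potential table needs columns r, U, F")
    pt <- potential_table(x0, dx, vals[, 2L], F = vals[, 3L],
                          r_core = r_core, r_cut = r_cut)
    chk <- force_from_potential(pt)$F
    tol <- 1e-6 * max(1, max(abs(chk)))
    if (max(abs(chk - pt$F)) > tol)
      stop("force column inconsistent with dU/dr of the potential column")
    pt
  } else {
    tab_fn(x0, dx, vals[, 2L], kind)
  }
}

config_defaults <- function() {
  sim <- sim_config()
  ibi <- ibi_config()
  ibi_flat <- ibi[setdiff(names(ibi), "sim")]
  list(sim = sim[names(sim)], ibi = ibi_flat)
}

#' Load simulation and IBI configuration from a YAML file
#'
#' Two optional top-level blocks, `sim` and `ibi`, whose keys mirror
#' [sim_config()] and [ibi_config()] one to one. Unknown keys are
#' rejected; omitted keys take the documented defaults; an empty file
#' yields all defaults.
#'
#' @param path YAML file path.
#' @return list with validated `sim` ([sim_config()]) and `ibi`
#'   ([ibi_config()]) entries.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c("sim", "ibi"))
  if (length(bad)) stop(sprintf("unknown config block '%s'", bad[1L]))
  defs <- config_defaults()
  check_block <- function(block, name) {
    if (is.null(block)) return(list())
    unknown <- setdiff(names(block), names(defs[[name]]))
    if (length(unknown))
      stop(sprintf("unknown key '%s' in config block '%s'", unknown[1L], name))
    for (k in names(block)) {
      want <- defs[[name]][[k]]
      if (is.numeric(want) && !is.numeric(block[[k]]))
        stop(sprintf("config key '%s' must be numeric", k))
      if (is.character(want) && !is.character(block[[k]]))
        stop(sprintf("config key '%s' must be a string", k))
    }
    block
  }
  sim_args <- check_block(raw$sim, "sim")
  sim_args$remove_com <- if (is.null(sim_args$remove_com)) TRUE else
    isTRUE(sim_args$remove_com)
  sim <- do.call(sim_config, sim_args)
  ibi_args <- check_block(raw$ibi, "ibi")
  ibi_args$sim <- sim
  list(sim = sim, ibi = do.call(ibi_config, ibi_args))
}

#' Save a configuration snapshot as YAML
#' @param config an [ibi_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ibi_config"))
  sim <- config$sim
  out <- list(sim = sim[names(sim)],
              ibi = config[setdiff(names(config), "sim")])
  out$ibi$iterate_pair <- as.list(out$ibi$iterate_pair)
  yaml::write_yaml(out, path)
  invisible(path)
}

write_manifest <- function(fit, out_dir) {
  n_iter <- length(fit$f_history)
  man <- data.frame(
    n = seq_len(n_iter) - 1L,
    f_target = fit$f_history,
    seed = vapply(fit$iterations, function(it) as.numeric(it$seed), numeric(1)),
    potential_file = sprintf("iter_%03d/potential.dat", seq_len(n_iter) - 1L),
    rdf_file = sprintf("iter_%03d/rdf.dat", seq_len(n_iter) - 1L))
  utils::write.csv(man, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(man[, c("n", "f_target")],
                   file.path(out_dir, "f_history.csv"), row.names = FALSE)
  write_config(fit$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Read an IBI iteration archive
#'
#' Validates that every referenced per-iteration file exists, locates
#' the best (minimum `f_target`) iteration and loads its tables along
#' with the configuration snapshot.
#'
#' @param dir archive directory written by [run_ibi()].
#' @return list with `manifest` (data.frame), `best_iteration` (row
#'   index 0-based), `f_history`, `potential`, `rdf`, and `config`.
#' @export
read_archive <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  paths <- file.path(dir, c(man$potential_file, man$rdf_file))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop(sprintf("archive file missing: %s", missing[1L]))
  best <- which.min(man$f_target)
  cfg <- load_config(file.path(dir, "config.yaml"))
  list(manifest = man, best_iteration = man$n[best],
       f_history = man$f_target,
       potential = read_table(file.path(dir, man$potential_file[best])),
       rdf = read_table(file.path(dir, man$rdf_file[best])),
       config = cfg$ibi)
}
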