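# Persistence: trajectory container (versioned plain text), energy series,
# coarse-grained PDB export, run configuration and checkpoints.

TRAJ_MAGIC <- "# primedmd trajectory v1"

#' Write a trajectory to a versioned plain-text container
#'
#' Stores per frame: clock time, reduced temperature, interaction and
#' kinetic energy, the hydrogen-bond list and all sphere positions at full
#' (hexadecimal) precision, so that reading the file back reproduces the
#' arrays bit-for-bit.
#'
#' @param frames list of frames (as produced by [dmd_run()])
#' @param path output file
#' @param n_spheres sphere count (taken from the first frame if omitted)
#' @export
write_trajectory <- function(frames, path, n_spheres = NULL) {
  if (is.null(n_spheres)) {
    n_spheres <- if (length(frames)) nrow(frames[[1]]$pos) else 0L
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(TRAJ_MAGIC, con)
  writeLines(sprintf("nspheres %d", n_spheres), con)
  writeLines(sprintf("nframes %d", length(frames)), con)
  num <- function(x) sprintf("%a", x)   # hex float: exact round trip
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    writeLines(sprintf("frame %d", k), con)
    writeLines(paste("time", num(f$time), "tstar", num(f$tstar),
                     "pe", num(f$pe), "ke", num(f$ke)), con)
    b <- f$bonds
    writeLines(sprintf("bonds %d", nrow(b)), con)
    if (nrow(b) > 0)
      writeLines(paste(b[, 1], b[, 2]), con)
    writeLines("pos", con)
    writeLines(paste(num(f$pos[, 1]), num(f$pos[, 2]), num(f$pos[, 3])), con)
  }
  invisible(path)
}

#' Read a trajectory container written by [write_trajectory()]
#' @param path input file
#' @return list of frames
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != TRAJ_MAGIC)
    stop("not a primedmd trajectory (bad or missing version header): ", path)
  n <- as.integer(sub("nspheres ", "", lines[2]))
  nf <- as.integer(sub("nframes ", "", lines[3]))
  if (is.na(n) || is.na(nf)) stop("corrupt trajectory header")
  i <- 4L
  need <- function(k) {
    if (i + k - 1L > length(lines)) stop("truncated trajectory file: ", path)
  }
  frames <- vector("list", nf)
  for (k in seq_len(nf)) {
    need(3L)
    if (!startsWith(lines[i], "frame ")) stop("corrupt frame header at line ", i)
    hdr <- strsplit(lines[i + 1L], " ")[[1]]
    vals <- strtoi_num(hdr[c(2, 4, 6, 8)])
    nb <- as.integer(sub("bonds ", "", lines[i + 2L]))
    i <- i + 3L
    need(nb + 1L + n)
    bonds <- if (nb > 0) {
      m <- do.call(rbind, strsplit(lines[i:(i + nb - 1L)], " "))
      matrix(as.integer(m), ncol = 2)
    } else matrix(integer(0), 0, 2)
    i <- i + nb
    if (lines[i] != "pos") stop("corrupt frame block at line ", i)
    i <- i + 1L
    m <- do.call(rbind, strsplit(lines[i:(i + n - 1L)], " "))
    pos <- matrix(strtoi_num(as.vector(m)), ncol = 3)
    i <- i + n
    frames[[k]] <- list(time = vals[1], tstar = vals[2], pe = vals[3],
                        ke = vals[4], pos = pos, bonds = bonds)
  }
  frames
}

# parse "%a" hex floats (and plain numbers)
strtoi_num <- function(x) {
  vapply(x, function(s) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop("bad numeric field '", s, "'")
    v
  }, numeric(1), USE.NAMES = FALSE)
}

#' Write an energy series as tab-separated text
#' @param energy data frame (columns `time`, `pe`, `ke`, `tstar`)
#' @param path output file
#' @export
write_energy_series <- function(energy, path) {
  write.table(energy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an energy series written by [write_energy_series()]
#' @param path input file
#' @export
read_energy_series <- function(path) {
  read.delim(path)
}

#' Export frames as a coarse-grained multi-model PDB
#'
#' Spheres map to atom records N (NH), CA (CaH), C (CO) and CB (side
#' sphere); residues carry standard three-letter names and the reported
#' numbering (17..42 for the Abeta fragment); one MODEL per frame.
#'
#' @param frames list of frames (or a single position matrix)
#' @param topology a `prime_topology`
#' @param path output file
#' @param first_residue number of the first residue in each chain
#' @export
export_pdb <- function(frames, topology, path,
                       first_residue = AB_FIRST_RESIDUE) {
  if (is.matrix(frames)) frames <- list(list(pos = frames))
  sp <- topology$spheres
  nres1 <- topology$n_residues
  atom_name <- c(NH = "N", CA = "CA", CO = "C", R = "CB")[sp$role]
  resno <- ((sp$residue - 1) %% nres1) + first_residue
  chain_id <- LETTERS[((sp$chain - 1) %% 26) + 1]
  resname <- three_letter[sp$letter]
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(frames)) {
    pos <- frame_pos(frames[[m]])
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      sp$id, sprintf(" %-3s", atom_name), resname, chain_id, resno,
      pos[, 1], pos[, 2], pos[, 3], 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write / read a run configuration (plain-text DCF)
#' @param config a `prime_config`
#' @param path file path
#' @export
write_run_config <- function(config, path) {
  df <- data.frame(lapply(unclass(config), function(x) format(x, digits = 17)))
  write.dcf(df, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  m <- read.dcf(path)
  simulation_config(n_chains = as.integer(m[1, "n_chains"]),
                    box_length = as.numeric(m[1, "box_length"]),
                    t_start = as.numeric(m[1, "t_start"]),
                    t_final = as.numeric(m[1, "t_final"]),
                    cool_events = as.numeric(m[1, "cool_events"]),
                    budget = as.numeric(m[1, "budget"]),
                    seed = as.integer(m[1, "seed"]))
}

#' Checkpoint a run to plain text and restore it
#'
#' Serializes the state, hydrogen-bond registry, executed-event count, the
#' next scheduled ghost-collision time and R's RNG state with exact
#' (hexadecimal) numeric encoding, so a restarted run continues
#' event-for-event identically.
#'
#' @param run a `prime_run`
#' @param path file path
#' @export
write_checkpoint <- function(run, path) {
  obj <- list(pos = run$state$pos, vel = run$state$vel,
              box = run$state$box, time = run$state$time,
              tstar = run$state$tstar,
              registry = run$registry,
              pair_events_total = run$pair_events_total,
              next_ghost_time = run$next_ghost_time,
              rng = .Random.seed)
  dput(obj, path, control = c("all", "hexNumeric"))
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- dget(path)
  assign(".Random.seed", obj$rng, envir = globalenv())
  state <- structure(list(pos = obj$pos, vel = obj$vel, box = obj$box,
                          time = obj$time, tstar = obj$tstar),
                     class = "prime_state")
  list(state = state, registry = obj$registry,
       pair_events_total = obj$pair_events_total,
       next_ghost_time = obj$next_ghost_time)
}

#' Read a sequence from a FASTA file or return the bare string
#' @param x path to a FASTA file, or a plain sequence string
#' @return one-letter sequence string
#' @export
read_sequence <- function(x) {
  if (file.exists(x)) {
    lines <- readLines(x)
    lines <- lines[!startsWith(lines, ">") & nzchar(lines)]
    return(toupper(paste(lines, collapse = "")))
  }
  toupper(x)
}
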