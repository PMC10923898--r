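## secondary_structure: internal Kabsch-Sander assignment and the 3-class
## collapse. Downstream code consumes only the helix/sheet/loop classes;
## the 8-state assignment follows the classic hydrogen-bond definitions.

backbone_coords <- function(model) {
  n <- model$n
  out <- list()
  for (nm in c("N", "CA", "C", "O")) {
    m <- matrix(NA_real_, n, 3)
    sel <- model$atoms$name == nm
    rows <- model$atoms[sel, , drop = FALSE]
    rows <- rows[!duplicated(rows$residue), , drop = FALSE]
    m[rows$residue, ] <- as.matrix(rows[, c("x", "y", "z")])
    missing <- which(!stats::complete.cases(m))
    if (length(missing))
      stop("missing backbone atom ", nm, " in residue ", missing[1])
    out[[nm]] <- m
  }
  out
}

## hbCO[a, b]: TRUE when the carbonyl of residue a accepts an H-bond from
## the amide of residue b. Energy E = 0.084 (1/rON + 1/rCH - 1/rOH - 1/rCN)
## x 332 kcal/mol; bond when E < -0.5.
ks_hbonds <- function(bb, sequence, cutoff = -0.5) {
  n <- nrow(bb$N)
  hb <- matrix(FALSE, n, n)
  if (n < 3) return(hb)
  ## amide H: 1.0 A from N, anti-parallel to the preceding carbonyl C=O
  H <- matrix(NA_real_, n, 3)
  d <- bb$C[-n, , drop = FALSE] - bb$O[-n, , drop = FALSE]
  d <- d / sqrt(rowSums(d^2))
  H[-1, ] <- bb$N[-1, , drop = FALSE] + d
  aa <- strsplit(sequence, "")[[1]]
  has_H <- c(FALSE, rep(TRUE, n - 1)) & aa != "P"

  q <- 0.084 * 332
  idx <- seq_len(n)
  for (a in idx) {
    dca <- sqrt(rowSums((bb$CA - matrix(bb$CA[a, ], n, 3, byrow = TRUE))^2))
    b <- which(dca < 9 & has_H & abs(idx - a) > 1)
    if (!length(b)) next
    Oa <- matrix(bb$O[a, ], length(b), 3, byrow = TRUE)
    Ca <- matrix(bb$C[a, ], length(b), 3, byrow = TRUE)
    rON <- sqrt(rowSums((Oa - bb$N[b, , drop = FALSE])^2))
    rCH <- sqrt(rowSums((Ca - H[b, , drop = FALSE])^2))
    rOH <- sqrt(rowSums((Oa - H[b, , drop = FALSE])^2))
    rCN <- sqrt(rowSums((Ca - bb$N[b, , drop = FALSE])^2))
    E <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    E[rON < 0.5 | rCH < 0.5 | rOH < 0.5 | rCN < 0.5] <- -9.9
    hb[a, b[E < cutoff]] <- TRUE
  }
  hb
}

## shift helpers: matrix M with rows/cols displaced, FALSE-padded
shift_rows <- function(M, by) {
  n <- nrow(M)
  out <- matrix(FALSE, n, n)
  if (by > 0) out[(by + 1):n, ] <- M[1:(n - by), , drop = FALSE]
  else if (by < 0) out[1:(n + by), ] <- M[(1 - by):n, , drop = FALSE]
  else out <- M
  out
}
shift_cols <- function(M, by) t(shift_rows(t(M), by))

#' Assign per-residue secondary structure
#'
#' Computes an 8-state secondary-structure string using the Kabsch-Sander
#' hydrogen-bond energy scheme: H/G/I helices from pairs of consecutive
#' n-turns (n = 4, 3, 5), B/E for isolated bridges and ladders, T for turn
#' interiors, S for bends (chain direction change above 70 degrees), and
#' "-" for irregular residues. An external `mkdssp`/`dssp` binary is used
#' instead when `backend = "external"`.
#'
#' @param model a `protein_model` with complete N, CA, C, O backbone.
#' @param backend `"internal"` (default) or `"external"`.
#' @return Object of class `ss_assignment`: list with `states8` and
#'   `states3` character vectors.
#' @export
assign_ss <- function(model, backend = c("internal", "external")) {
  backend <- match.arg(backend)
  if (backend == "external") return(assign_ss_external(model))
  bb <- backbone_coords(model)
  n <- model$n
  s8 <- rep("-", n)
  if (n >= 3) {
    hb <- ks_hbonds(bb, model$sequence)
    turn <- list()
    for (k in 3:5) {
      t_ <- rep(FALSE, n)
      if (n - k >= 1) {
        i <- seq_len(n - k)
        t_[i] <- hb[cbind(i, i + k)]
      }
      turn[[as.character(k)]] <- t_
    }
    claim <- function(state, pos) {
      pos <- pos[pos >= 1 & pos <= n]
      s8[pos[s8[pos] == "-"]] <<- state
    }
    ## alpha helix: two consecutive 4-turns starting at i-1 and i
    for (i in which(turn[["4"]])) {
      if (i > 1 && turn[["4"]][i - 1]) claim("H", i:(i + 3))
    }
    ## bridges (vectorized Kabsch-Sander conditions)
    tb <- t(hb)
    para <- (shift_rows(hb, 1) & shift_rows(tb, -1)) |
      (shift_cols(tb, 1) & shift_cols(hb, -1))
    anti <- (hb & tb) |
      (shift_cols(shift_rows(hb, 1), -1) & shift_cols(shift_rows(tb, -1), 1))
    sep_ok <- outer(seq_len(n), seq_len(n), function(i, j) j - i >= 3)
    interior <- seq_len(n) > 1 & seq_len(n) < n
    valid <- sep_ok & outer(interior, interior, `&`)
    bridges <- which(valid & (para | anti), arr.ind = TRUE)
    if (nrow(bridges)) {
      type <- ifelse((para & valid)[bridges], 1L, 2L)
      key <- function(i, j, ty) paste(i, j, ty)
      keys <- key(bridges[, 1], bridges[, 2], type)
      in_ladder <- rep(FALSE, nrow(bridges))
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        in_ladder <- in_ladder |
          key(bridges[, 1] + di, bridges[, 2] + dj, type) %in% keys
      }
      for (r in order(!in_ladder)) {  # ladders (E) before isolated (B)
        st <- if (in_ladder[r]) "E" else "B"
        pos <- bridges[r, 1:2]
        s8[pos[s8[pos] == "-"]] <- st
      }
    }
    ## 3-helix and 5-helix
    for (i in which(turn[["3"]])) {
      if (i > 1 && turn[["3"]][i - 1]) claim("G", i:(i + 2))
    }
    for (i in which(turn[["5"]])) {
      if (i > 1 && turn[["5"]][i - 1]) claim("I", i:(i + 4))
    }
    ## turns: interior residues of any single n-turn
    for (k in 3:5) {
      for (i in which(turn[[as.character(k)]])) claim("T", (i + 1):(i + k - 1))
    }
    ## bends
    if (n >= 5) {
      i <- 3:(n - 2)
      u <- bb$CA[i, , drop = FALSE] - bb$CA[i - 2, , drop = FALSE]
      v <- bb$CA[i + 2, , drop = FALSE] - bb$CA[i, , drop = FALSE]
      cosang <- rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2))
      bend <- i[acos(pmin(1, pmax(-1, cosang))) > 70 * pi / 180]
      s8[bend[s8[bend] == "-"]] <- "S"
    }
  }
  structure(list(states8 = s8, states3 = collapse_3class(s8)),
            class = "ss_assignment")
}

assign_ss_external <- function(model) {
  exe <- Sys.which(c("mkdssp", "dssp"))
  exe <- exe[exe != ""]
  if (!length(exe))
    stop("no external DSSP binary (mkdssp/dssp) found on PATH; ",
         "use backend = \"internal\"")
  pdb <- tempfile(fileext = ".pdb")
  out <- tempfile(fileext = ".dssp")
  on.exit(unlink(c(pdb, out)), add = TRUE)
  write_pdb(model, pdb)
  status <- system2(exe[[1]], c(pdb, out), stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("external DSSP failed with status ", status)
  lines <- readLines(out, warn = FALSE)
  start <- grep("^  #  RESIDUE", lines)
  if (!length(start)) stop("unparseable DSSP output")
  body <- lines[(start + 1):length(lines)]
  body <- body[substr(body, 14, 14) != "!"]
  s8 <- substr(body, 17, 17)
  s8[s8 == " "] <- "-"
  s8[s8 == "P"] <- "-"  # polyproline-II from modern DSSP -> irregular
  if (length(s8) != model$n)
    stop("DSSP returned ", length(s8), " states for ", model$n, " residues")
  structure(list(states8 = s8, states3 = collapse_3class(s8)),
            class = "ss_assignment")
}

#' Collapse 8-state secondary structure to helix/sheet/loop
#'
#' H, G and I map to helix; B and E to sheet; S, T and irregular ("-",
#' also accepted as " " or "C") to loop.
#'
#' @param states8 character vector of 8-state symbols.
#' @return Character vector over `c("helix", "sheet", "loop")`.
#' @export
collapse_3class <- function(states8) {
  if (!length(states8)) return(character(0))
  out <- rep(NA_character_, length(states8))
  out[states8 %in% c("H", "G", "I")] <- "helix"
  out[states8 %in% c("B", "E")] <- "sheet"
  out[states8 %in% c("S", "T", "-", " ", "C")] <- "loop"
  if (anyNA(out))
    stop("unknown secondary-structure symbol: ",
         paste(unique(states8[is.na(out)]), collapse = ", "))
  out
}
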