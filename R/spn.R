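#' Construct an extended stochastic Petri net
#'
#' An SPN is a bipartite graph of places (biological species, holding integer
#' token counts) and transitions (reactions), joined by weighted arcs of four
#' kinds. A \code{standard} arc from place to transition consumes tokens on
#' firing and requires \code{m[p] >= w} to enable; an \code{inhibitor} arc
#' enables only while \code{m[p] < w}; a \code{read} arc requires
#' \code{m[p] >= w}; an \code{equal} arc requires \code{m[p] == w}. Inhibitor,
#' read and equal arcs never consume tokens and must run place to transition.
#' Standard arcs from transition to place deposit tokens.
#'
#' @param places data frame with columns \code{id} (unique character),
#'   optionally \code{label} and \code{capacity} (positive integer or NA for
#'   unbounded), or a character vector of ids.
#' @param transitions data frame with columns \code{id} and optionally
#'   \code{label}, or a character vector of ids.
#' @param arcs data frame with columns \code{source}, \code{target},
#'   \code{kind} (one of \code{"standard"}, \code{"inhibitor"}, \code{"read"},
#'   \code{"equal"}; defaults to standard) and \code{weight} (positive
#'   integer, defaults to 1).
#' @param name optional net name.
#' @param check validate structural invariants and stop on violation.
#' @return An object of class \code{"spn"}.
#' @examples
#' net <- spn(c("A", "B"), c("fwd", "rev"),
#'            data.frame(source = c("A", "fwd", "B", "rev"),
#'                       target = c("fwd", "B", "rev", "A")))
#' is_enabled(net, spn_marking(net, c(A = 1)), "fwd")
#' @export
spn <- function(places, transitions, arcs, name = "net", check = TRUE) {
  if (is.character(places))
    places <- data.frame(id = places, stringsAsFactors = FALSE)
  if (is.character(transitions))
    transitions <- data.frame(id = transitions, stringsAsFactors = FALSE)
  places <- as.data.frame(places, stringsAsFactors = FALSE)
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  if (is.null(places$label)) places$label <- places$id
  if (is.null(places$capacity)) places$capacity <- NA_integer_
  if (is.null(transitions$label)) transitions$label <- transitions$id
  arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
  if (is.null(arcs$kind)) arcs$kind <- "standard"
  if (is.null(arcs$weight)) arcs$weight <- 1L
  arcs$weight <- as.integer(arcs$weight)
  net <- structure(list(name = name,
                        places = places[c("id", "label", "capacity")],
                        transitions = transitions[c("id", "label")],
                        arcs = arcs[c("source", "target", "kind", "weight")]),
                   class = "spn")
  if (check) {
    v <- validate_spn(net)
    if (length(v))
      stop("invalid net: ", paste(v, collapse = "; "))
  }
  net
}

ARC_KINDS <- c("standard", "inhibitor", "read", "equal")

#' Validate the structural invariants of a net
#'
#' Checks id uniqueness and namespace disjointness, capacities, arc
#' bipartiteness, arc direction restrictions for the non-consuming kinds,
#' positive integer weights, dangling endpoints and duplicate
#' (source, target, kind) triples. Violations are described, not raised.
#'
#' @param net an \code{spn} (possibly built with \code{check = FALSE}).
#' @return character vector of violation descriptions; empty when the net is
#'   well formed.
#' @export
validate_spn <- function(net) {
  v <- character()
  p <- net$places; tr <- net$transitions; a <- net$arcs
  if (nrow(p) == 0L) v <- c(v, "net has no places")
  if (nrow(tr) == 0L) v <- c(v, "net has no transitions")
  if (anyDuplicated(p$id))
    v <- c(v, paste("duplicate place ids:",
                    paste(unique(p$id[duplicated(p$id)]), collapse = ", ")))
  if (anyDuplicated(tr$id))
    v <- c(v, paste("duplicate transition ids:",
                    paste(unique(tr$id[duplicated(tr$id)]), collapse = ", ")))
  shared <- intersect(p$id, tr$id)
  if (length(shared))
    v <- c(v, paste("ids used for both a place and a transition:",
                    paste(shared, collapse = ", ")))
  bad_cap <- !is.na(p$capacity) & (p$capacity < 1 | p$capacity != round(p$capacity))
  if (any(bad_cap))
    v <- c(v, paste("place", p$id[bad_cap], "has capacity < 1"))
  for (i in seq_len(nrow(a))) {
    src <- a$source[i]; tgt <- a$target[i]
    lab <- sprintf("arc %s -> %s (%s)", src, tgt, a$kind[i])
    sp <- src %in% p$id; st <- src %in% tr$id
    tp <- tgt %in% p$id; tt <- tgt %in% tr$id
    if (!(sp || st)) v <- c(v, paste(lab, ": unknown source id", src))
    if (!(tp || tt)) v <- c(v, paste(lab, ": unknown target id", tgt))
    if ((sp && tp) || (st && tt))
      v <- c(v, paste(lab, ": arc must join a place and a transition"))
    if (!a$kind[i] %in% ARC_KINDS)
      v <- c(v, paste(lab, ": unknown arc kind", a$kind[i]))
    if (a$kind[i] %in% c("inhibitor", "read", "equal") && !(sp && tt))
      v <- c(v, paste(lab, ": a", a$kind[i],
                      "arc may only run from a place to a transition"))
    if (is.na(a$weight[i]) || a$weight[i] < 1)
      v <- c(v, paste(lab, ": weight must be a positive integer"))
  }
  key <- paste(a$source, a$target, a$kind)
  if (anyDuplicated(key))
    v <- c(v, paste("duplicate arcs:",
                    paste(unique(key[duplicated(key)]), collapse = "; ")))
  v
}

#' @export
#' @method print spn
print.spn <- function(x, ...) {
  cat(sprintf("Stochastic Petri net '%s': %d places, %d transitions, %d arcs\n",
              x$name, nrow(x$places), nrow(x$transitions), nrow(x$arcs)))
  kinds <- table(factor(x$arcs$kind, levels = ARC_KINDS))
  cat("  arcs by kind:",
      paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @method summary spn
summary.spn <- function(object, ...) {
  print(object)
  cat("  places:", paste(utils::head(object$places$id, 12L), collapse = ", "),
      if (nrow(object$places) > 12L) "..." else "", "\n")
  cat("  transitions:",
      paste(utils::head(object$transitions$id, 12L), collapse = ", "),
      if (nrow(object$transitions) > 12L) "..." else "", "\n")
  invisible(object)
}

#' Build a complete marking for a net
#'
#' @param net an \code{spn}.
#' @param counts named numeric vector of token counts; places not named are
#'   set to 0.
#' @return named integer vector over all places, in net place order.
#' @export
spn_marking <- function(net, counts = numeric()) {
  m <- stats::setNames(integer(nrow(net$places)), net$places$id)
  if (length(counts)) {
    unknown <- setdiff(names(counts), net$places$id)
    if (length(unknown))
      stop("unknown places in marking: ", paste(unknown, collapse = ", "))
    m[names(counts)] <- as.integer(counts)
  }
  if (any(m < 0)) stop("marking has negative counts")
  cap <- net$places$capacity
  over <- !is.na(cap) & m > cap
  if (any(over))
    stop("marking exceeds capacity at: ",
         paste(net$places$id[over], collapse = ", "))
  m
}

arcs_into <- function(net, t) net$arcs[net$arcs$target == t, , drop = FALSE]
arcs_from <- function(net, t) net$arcs[net$arcs$source == t, , drop = FALSE]

## net token change of firing t, as a named vector over all places
firing_delta <- function(net, t) {
  d <- stats::setNames(integer(nrow(net$places)), net$places$id)
  ain <- arcs_into(net, t)
  std_in <- ain[ain$kind == "standard", , drop = FALSE]
  if (nrow(std_in)) d[std_in$source] <- d[std_in$source] - std_in$weight
  aout <- arcs_from(net, t)
  if (nrow(aout)) d[aout$target] <- d[aout$target] + aout$weight
  d
}

#' Is a transition enabled under a marking?
#'
#' A transition is enabled when every standard and read input arc finds at
#' least its weight in tokens, every inhibitor arc finds fewer than its
#' weight, every equal arc finds exactly its weight, and firing would not
#' push any post-place above its capacity.
#'
#' @param net an \code{spn}.
#' @param m marking from \code{\link{spn_marking}}.
#' @param t transition id.
#' @return logical scalar.
#' @export
is_enabled <- function(net, m, t) {
  if (!t %in% net$transitions$id) stop("unknown transition: ", t)
  ain <- arcs_into(net, t)
  for (i in seq_len(nrow(ain))) {
    tok <- m[[ain$source[i]]]; w <- ain$weight[i]
    ok <- switch(ain$kind[i],
                 standard = tok >= w,
                 read = tok >= w,
                 inhibitor = tok < w,
                 equal = tok == w)
    if (!ok) return(FALSE)
  }
  new_m <- m + firing_delta(net, t)
  cap <- net$places$capacity
  !any(!is.na(cap) & new_m > cap)
}

#' Fire a transition
#'
#' Standard input arcs subtract their weight, standard output arcs add
#' theirs; read, inhibitor and equal arcs leave the marking untouched.
#' Firing a disabled transition is an error.
#'
#' @inheritParams is_enabled
#' @return the successor marking.
#' @export
fire <- function(net, m, t) {
  if (!is_enabled(net, m, t))
    stop("transition ", t, " is not enabled")
  m2 <- m + firing_delta(net, t)
  stopifnot(all(m2 >= 0))
  m2
}

#' Incidence matrix of a net
#'
#' Entry \code{[p, t]} is the net token change of place \code{p} when
#' transition \code{t} fires: standard output weights minus standard input
#' weights. Read, inhibitor and equal arcs contribute nothing.
#'
#' @param net an \code{spn}.
#' @return integer matrix, places by transitions, with dimnames.
#' @export
incidence_matrix <- function(net) {
  C <- matrix(0L, nrow(net$places), nrow(net$transitions),
              dimnames = list(net$places$id, net$transitions$id))
  for (t in net$transitions$id) C[, t] <- firing_delta(net, t)
  C
}

vec_gcd <- function(x) {
  g2 <- function(a, b) if (b == 0) a else g2(b, a %% b)
  Reduce(g2, abs(x[x != 0]), accumulate = FALSE)
}

#' Place invariants of a net
#'
#' Computes a generating set of minimal-support non-negative integer vectors
#' \code{y} with \code{t(y) \%*\% incidence_matrix(net) == 0}. Along every
#' trajectory the weighted token sum \code{sum(y * marking)} is then
#' conserved; the shipped disease models use these to assert mass
#' conservation of calcium, sodium, potassium, Calpain and CAST pools.
#' Uses Farkas-style column elimination with a cap on the number of
#' intermediate candidate vectors.
#'
#' @param net an \code{spn}.
#' @param max_rows abort if the intermediate vector count exceeds this.
#' @return integer matrix with one invariant per row (columns = places);
#'   zero rows when none exist.
#' @export
p_invariants <- function(net, max_rows = 20000L) {
  C <- incidence_matrix(net)
  nP <- nrow(C); nT <- ncol(C)
  D <- cbind(C, diag(nP))
  for (j in seq_len(nT)) {
    col <- D[, j]
    zero <- D[col == 0, , drop = FALSE]
    pos <- D[col > 0, , drop = FALSE]
    neg <- D[col < 0, , drop = FALSE]
    comb <- NULL
    if (nrow(pos) && nrow(neg)) {
      rows <- vector("list", nrow(pos) * nrow(neg))
      k <- 0L
      for (ia in seq_len(nrow(pos))) {
        for (ib in seq_len(nrow(neg))) {
          pa <- pos[ia, j]; nb <- -neg[ib, j]
          g2 <- vec_gcd(c(pa, nb))
          r <- (nb / g2) * pos[ia, ] + (pa / g2) * neg[ib, ]
          g <- vec_gcd(r)
          if (!is.null(g) && g > 1) r <- r / g
          k <- k + 1L
          rows[[k]] <- r
        }
      }
      comb <- do.call(rbind, rows[seq_len(k)])
    }
    D <- rbind(zero, comb)
    if (nrow(D)) D <- D[!duplicated(D), , drop = FALSE]
    if (nrow(D) > max_rows)
      stop("p_invariants: intermediate vector count exceeded cap (",
           max_rows, ")")
  }
  Y <- D[, nT + seq_len(nP), drop = FALSE]
  if (nrow(Y)) {
    Y <- Y[rowSums(abs(Y)) > 0, , drop = FALSE]
    Y <- Y[!duplicated(Y), , drop = FALSE]
    Y <- Y[minimal_support_idx(Y), , drop = FALSE]
  }
  colnames(Y) <- rownames(C)
  storage.mode(Y) <- "integer"
  Y
}

## index version of minimal_support, used on the invariant part only
minimal_support_idx <- function(Y) {
  n <- nrow(Y)
  if (n <= 1L) return(seq_len(n))
  supp <- Y != 0
  sz <- rowSums(supp)
  ord <- order(sz)
  keep <- rep(TRUE, n)
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    if (!keep[i]) next
    for (b in seq((a + 1L), n)) {
      j <- ord[b]
      if (!keep[j]) next
      if (sz[j] > sz[i] && all(supp[i, ] <= supp[j, ])) keep[j] <- FALSE
    }
  }
  which(keep)
}
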