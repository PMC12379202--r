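#' Energy windows for three-photon event selection
#'
#' Closed keV intervals for the two annihilation photons and the 602.73 keV
#' prompt photon; boundary values are accepted.
#'
#' @param annihilation length-2 closed interval (keV).
#' @param prompt length-2 closed interval (keV).
#' @return An object of class `energy_windows`.
#' @export
energy_windows <- function(annihilation = c(460, 545), prompt = c(568, 639)) {
  stopifnot(length(annihilation) == 2L, length(prompt) == 2L)
  stopifnot(annihilation[1] < annihilation[2], prompt[1] < prompt[2])
  if (max(annihilation[1], prompt[1]) <= min(annihilation[2], prompt[2])) {
    stop("annihilation and prompt windows must not overlap")
  }
  structure(list(annihilation = as.numeric(annihilation),
                 prompt = as.numeric(prompt)),
            class = "energy_windows")
}

#' Classify single-photon energies
#'
#' @param energy numeric vector of deposited energies (keV), positive.
#' @param windows an [energy_windows()].
#' @return Character vector: `"annihilation"`, `"prompt"`, or `"reject"`.
#' @export
classify_energy <- function(energy, windows = energy_windows()) {
  stopifnot(all(energy > 0))
  out <- rep("reject", length(energy))
  out[energy >= windows$annihilation[1] & energy <= windows$annihilation[2]] <-
    "annihilation"
  out[energy >= windows$prompt[1] & energy <= windows$prompt[2]] <- "prompt"
  out
}

# greedy time clustering: a cluster is the maximal run of records within
# `width` of its first record; returns integer cluster ids
cluster_by_time <- function(t, width) {
  n <- length(t)
  cl <- integer(n)
  i <- 1L
  k <- 0L
  while (i <= n) {
    k <- k + 1L
    j <- findInterval(t[i] + width, t)
    cl[i:j] <- k
    i <- j + 1L
  }
  cl
}

#' Build three-photon events from a time-sorted singles stream
#'
#' Records are grouped greedily into coincidence clusters (all records
#' within `coincidence_width` of the first record of the cluster). A
#' cluster yields one three-photon event exactly when it contains exactly
#' two photons in the annihilation window and exactly one in the prompt
#' window; clusters with extra in-window photons are discarded as
#' ambiguous (out-of-window photons in a cluster are ignored). For each
#' accepted event the annihilation vertex is TOF-localized on the line of
#' response and the vertex-corrected annihilation-minus-prompt time
#' difference is computed.
#'
#' @param singles singles tibble sorted by `t_ns` (unsorted input is an
#'   error).
#' @param windows an [energy_windows()].
#' @param coincidence_width coincidence window (ns); the default 15 ns
#'   covers prompt-to-annihilation delays across the full fitted
#'   time-difference range with margin.
#' @return Tibble of three-photon events: `vx`, `vy`, `vz` (mm),
#'   `delta_t` (ns), `tag` (`"random"` if any constituent single is an
#'   injected random, else `"annih"`), `event_id` (generative id of the
#'   prompt photon, if present in the input) and `pure` (all three photons
#'   from the same generative decay). Attribute `"n_clusters"` reports the
#'   number of coincidence clusters examined.
#' @export
build_3g_events <- function(singles, windows = energy_windows(),
                            coincidence_width = 15) {
  stopifnot(coincidence_width > 0)
  if (is.unsorted(singles$t_ns)) stop("singles must be sorted by t_ns")
  n <- nrow(singles)
  empty <- tibble::tibble(vx = double(), vy = double(), vz = double(),
                          delta_t = double(), tag = character(),
                          event_id = integer(), pure = logical())
  if (n == 0L) return(structure(empty, n_clusters = 0L))

  cls <- classify_energy(singles$E_keV, windows)
  cl <- cluster_by_time(singles$t_ns, coincidence_width)
  n_cl <- cl[n]
  n_ann <- tabulate(cl[cls == "annihilation"], nbins = n_cl)
  n_pro <- tabulate(cl[cls == "prompt"], nbins = n_cl)
  ok <- which(n_ann == 2L & n_pro == 1L)
  if (!length(ok)) return(structure(empty, n_clusters = n_cl))

  in_ok <- cl %in% ok
  ia <- which(in_ok & cls == "annihilation")
  ipr <- which(in_ok & cls == "prompt")
  # singles are time-sorted, so ia holds each cluster's pair in time order
  a1 <- ia[seq(1L, length(ia), by = 2L)]
  a2 <- ia[seq(2L, length(ia), by = 2L)]
  pos <- as.matrix(singles[, c("x_mm", "y_mm", "z_mm")])

  v <- localize_tof(pos[a1, , drop = FALSE], singles$t_ns[a1],
                    pos[a2, , drop = FALSE], singles$t_ns[a2])
  dt <- time_difference(v, pos[a1, , drop = FALSE], singles$t_ns[a1],
                        pos[a2, , drop = FALSE], singles$t_ns[a2],
                        pos[ipr, , drop = FALSE], singles$t_ns[ipr])

  tag <- ifelse(singles$tag[a1] == "random" | singles$tag[a2] == "random" |
                  singles$tag[ipr] == "random", "random", "annih")
  if ("event_id" %in% names(singles)) {
    eid <- singles$event_id[ipr]
    # pure: all three photons stem from the same generative decay (pile-up
    # of separate decays inside one cluster produces mispaired triples,
    # which are random coincidences by nature)
    pure <- !is.na(eid) & singles$event_id[a1] == eid &
      singles$event_id[a2] == eid
    pure[is.na(pure)] <- FALSE
  } else {
    eid <- rep(NA_integer_, length(ok))
    pure <- rep(NA, length(ok))
  }
  structure(
    tibble::tibble(vx = v[, 1], vy = v[, 2], vz = v[, 3], delta_t = dt,
                   tag = tag, event_id = eid, pure = pure),
    n_clusters = n_cl
  )
}

#' TOF localization of the annihilation vertex
#'
#' Places the vertex on the line of response between the two annihilation
#' crystals: starting from the chord midpoint, the vertex is displaced by
#' `(c/2) * (t_b - t_a)` towards the earlier-hit crystal (the photon
#' arriving later travelled farther), and clamped to the chord.
#'
#' @param pos_a,pos_b n-by-3 matrices of crystal positions (mm).
#' @param t_a,t_b detection times (ns).
#' @return n-by-3 matrix of vertex positions (mm).
#' @export
localize_tof <- function(pos_a, t_a, pos_b, t_b) {
  pos_a <- rbind(pos_a); pos_b <- rbind(pos_b)
  d <- pos_b - pos_a
  len <- sqrt(rowSums(d^2))
  if (any(len < 1e-9)) stop("coincident crystals: cannot localize")
  u <- d / len
  disp <- -(C_MM_PER_NS / 2) * (t_b - t_a)
  disp <- pmin(pmax(disp, -len / 2), len / 2)
  (pos_a + pos_b) / 2 + disp * u
}

#' Vertex-corrected annihilation-minus-prompt time difference
#'
#' Both times are propagated back to the vertex: the annihilation time is
#' the mean of the two crystal times minus their vertex flight times, and
#' the prompt emission time is the prompt crystal time minus its vertex
#' flight time (the TOF vertex doubles as the prompt emission point,
#' positron range being neglected). On noiseless data all flight times
#' cancel and the result equals the generative annihilation delay.
#'
#' @param vertex n-by-3 vertex matrix from [localize_tof()].
#' @param pos_a,t_a,pos_b,t_b annihilation crystal positions and times.
#' @param pos_p,t_p prompt crystal position and time.
#' @return Numeric vector of time differences (ns).
#' @export
time_difference <- function(vertex, pos_a, t_a, pos_b, t_b, pos_p, t_p) {
  vertex <- rbind(vertex)
  da <- row_dist(rbind(pos_a), vertex)
  db <- row_dist(rbind(pos_b), vertex)
  dp <- row_dist(rbind(pos_p), vertex)
  t_ann <- 0.5 * ((t_a - da / C_MM_PER_NS) + (t_b - db / C_MM_PER_NS))
  t_prompt_emit <- t_p - dp / C_MM_PER_NS
  t_ann - t_prompt_emit
}
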