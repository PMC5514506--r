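#' Shoving: one overlap-removal pass
#'
#' For every pair of cells whose centre distance is below
#' `(1 + shove_threshold_frac) * (r_i + r_j)` a symmetric repulsive
#' displacement proportional to the overlap is applied along the centre
#' line (equal and opposite for the two cells, `shove_k/2` of the overlap
#' each). Coincident centres are separated along a random direction.
#' Domain walls are hard (positions clamped).
#'
#' @param agents agent tibble.
#' @param species species parameter tibble.
#' @param cfg a [world_config].
#' @return list with the updated `agents` and `max_disp`, the largest
#'   single displacement of the pass (um).
#' @export
shove_pass <- function(agents, species, cfg) {
  r <- agent_radii(agents, species, cfg)
  res <- shove_pass_cpp(agents$x, agents$y, r, cfg$shove_k,
                        cfg$shove_threshold_frac,
                        cfg$domain_width, cfg$domain_height)
  agents$x <- res$x
  agents$y <- res$y
  list(agents = agents, max_disp = res$max_disp,
       dx = res$dx, dy = res$dy)
}

#' Adhesion: one attraction pass
#'
#' Pairs separated by less than `(1 + adhesion_range_frac) * (r_i + r_j)`
#' but not yet in contact move toward each other by a fraction of the
#' gap. Same-species pairs use `adhesion_hom`, cross-species pairs
#' `adhesion_het`; with both zero the pass is the identity.
#'
#' @inheritParams shove_pass
#' @return updated agent tibble.
#' @export
adhesion_pass <- function(agents, species, cfg) {
  r <- agent_radii(agents, species, cfg)
  sp <- match(agents$species, species$name)
  res <- adhesion_pass_cpp(agents$x, agents$y, r, as.integer(sp),
                           cfg$adhesion_hom, cfg$adhesion_het,
                           cfg$adhesion_range_frac, cfg$adhesion_range_min,
                           cfg$shove_threshold_frac,
                           cfg$domain_width, cfg$domain_height)
  agents$x <- res$x
  agents$y <- res$y
  agents
}

#' Mechanical relaxation to pseudo-steady state
#'
#' Alternates shoving and adhesion passes until the largest single
#' displacement falls below `tol` or the pass cap is hit.
#'
#' @inheritParams shove_pass
#' @param tol stopping displacement, um.
#' @param use_adhesion include adhesion passes.
#' @return relaxed agent tibble. The attributes `passes` and `capped`
#'   report the iteration count and whether the cap was hit.
#' @export
relax <- function(agents, species, cfg, tol = cfg$relax_tol,
                  use_adhesion = TRUE) {
  if (nrow(agents) < 2) return(agents)
  r <- agent_radii(agents, species, cfg)
  sp <- match(agents$species, species$name)
  res <- relax_cpp(agents$x, agents$y, r, as.integer(sp),
                   cfg$shove_k, cfg$shove_threshold_frac,
                   cfg$adhesion_hom, cfg$adhesion_het,
                   cfg$adhesion_range_frac, cfg$adhesion_range_min,
                   tol, cfg$relax_max_pass,
                   cfg$domain_width, cfg$domain_height, use_adhesion)
  agents$x <- res$x
  agents$y <- res$y
  attr(agents, "passes") <- res$passes
  attr(agents, "capped") <- res$capped
  agents
}

#' Contact-graph connected components
#'
#' Two cells are in contact when their centre distance is at most
#' `(1 + slack_frac) * (r_i + r_j) + reach_min`.
#'
#' @inheritParams shove_pass
#' @param slack_frac contact slack fraction.
#' @param reach_min absolute slack, um.
#' @return integer component label per agent (1-based).
#' @export
contact_components <- function(agents, species, cfg,
                               slack_frac = cfg$shove_threshold_frac,
                               reach_min = 0) {
  if (nrow(agents) == 0) return(integer())
  r <- agent_radii(agents, species, cfg)
  components_cpp(agents$x, agents$y, r, slack_frac, reach_min)
}

#' Random agitation (reactor scenario)
#'
#' Each agglomerate (connected component of the contact graph) receives
#' one random rigid displacement drawn from a centred normal with
#' standard deviation `strength`, which preserves formed granules;
#' isolated cells are their own components and move independently. On
#' top of the rigid motion every cell receives a small independent
#' jitter (`agitation_jitter_frac` x `strength`), so agglomerates not
#' held together by adhesion slowly erode. Displacements are clamped so
#' no member leaves the domain (reflective walls).
#'
#' @inheritParams shove_pass
#' @param strength displacement scale, um; 0 is the identity.
#' @return updated agent tibble.
#' @export
agitate <- function(agents, species, cfg,
                    strength = cfg$agitation_strength) {
  stopifnot(strength >= 0)
  n <- nrow(agents)
  if (n == 0 || strength == 0) return(agents)
  # cells within the adhesion reach are tethered and move as one body;
  # without adhesion only touching cells do
  adhesion_on <- cfg$adhesion_hom > 0 || cfg$adhesion_het > 0
  comp <- if (adhesion_on) {
    contact_components(agents, species, cfg,
                       slack_frac = cfg$shove_threshold_frac +
                         cfg$adhesion_range_frac,
                       reach_min = cfg$adhesion_range_min)
  } else {
    contact_components(agents, species, cfg)
  }
  k <- max(comp)
  sx <- rnorm(k, 0, strength)
  sy <- rnorm(k, 0, strength)
  r <- agent_radii(agents, species, cfg)
  for (c in seq_len(k)) {
    idx <- which(comp == c)
    # clamp the rigid shift so the whole component stays inside
    lo_x <- max(r[idx] - agents$x[idx])
    hi_x <- min(cfg$domain_width - r[idx] - agents$x[idx])
    lo_y <- max(r[idx] - agents$y[idx])
    hi_y <- min(cfg$domain_height - r[idx] - agents$y[idx])
    dx <- min(max(sx[c], lo_x), hi_x)
    dy <- min(max(sy[c], lo_y), hi_y)
    agents$x[idx] <- agents$x[idx] + dx
    agents$y[idx] <- agents$y[idx] + dy
  }
  jit <- cfg$agitation_jitter_frac * strength
  if (jit > 0) {
    agents$x <- agents$x + rnorm(n, 0, jit)
    agents$y <- agents$y + rnorm(n, 0, jit)
    agents$x <- pmin(pmax(agents$x, r), cfg$domain_width - r)
    agents$y <- pmin(pmax(agents$y, r), cfg$domain_height - r)
  }
  agents
}

#' Largest residual pairwise overlap (brute force)
#'
#' All-pairs oracle used to verify relaxation: returns the largest
#' physical overlap `r_i + r_j - d`, in um (negative when every pair is
#' separated). `slack_frac` widens the contact distance, e.g. to the
#' shove engagement threshold.
#'
#' @inheritParams shove_pass
#' @param slack_frac contact slack fraction (0 = true contact).
#' @return numeric scalar, um.
#' @export
max_pair_overlap <- function(agents, species, cfg, slack_frac = 0) {
  if (nrow(agents) < 2) return(-Inf)
  r <- agent_radii(agents, species, cfg)
  max_overlap_cpp(agents$x, agents$y, r, slack_frac)
}
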