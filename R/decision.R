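# Per-agent, per-frame behaviour selection.
#
# Passive behaviours (crowd repulsion, the fixed walking speed, no
# information exchange) apply to every agent all the time.  The single
# active locomotion behaviour is chosen from the agent's type and its group
# status: an agent within an arm's length (0.7 m = 14 px) of at least one
# other agent is "in the group"; one that has lost contact must return to
# the group before anything else, because the instruction subordinates the
# target to "without leaving the group".

#' Assess an agent's group status
#'
#' @param agent_id Id of the focal agent (matched against `agents$id`).
#' @param agents Agent data frame as built by [initialise_agents()]; must
#'   contain the focal agent.
#' @param arms_length Arm's-length trigger distance in pixels (default 14 =
#'   0.7 m): the agent is in the group iff at least one other agent is within
#'   this distance.  A single-agent world is in the group by convention.
#' @param group_range Group perception range in pixels (default 100 = 5 m):
#'   other agents within this range are the neighbours used by the
#'   keep-in-group rule.
#' @return A list with `in_group` (logical), `neighbours` (ids of agents
#'   within `group_range`) and `nearest_distance` (px; `Inf` when alone).
#' @export
assess_status <- function(agent_id, agents, arms_length = 14,
                          group_range = 100) {
  i <- match(agent_id, agents$id)
  if (is.na(i)) stop("agent_id not found in agents")
  n <- nrow(agents)
  if (n == 1L) {
    return(list(in_group = TRUE, neighbours = integer(0),
                nearest_distance = Inf))
  }
  d <- sqrt((agents$x - agents$x[i])^2 + (agents$y - agents$y[i])^2)
  d[i] <- Inf
  list(in_group = min(d) <= arms_length,
       neighbours = agents$id[d <= group_range],
       nearest_distance = min(d))
}

#' Select the behaviours an agent performs this frame
#'
#' Under the default `"strict_flowchart"` policy exactly one active
#' locomotion behaviour fires, plus the always-on passive repulsion:
#' \itemize{
#'   \item informed, in group: `seek_to` (its target number);
#'   \item informed, out of group: `keep_in_group` (returning to the group
#'     takes precedence over the target);
#'   \item uninformed, in group: `wander`;
#'   \item uninformed, out of group: `keep_in_group`.
#' }
#' The `"blend"` policy lets an informed agent out of group range perform
#' seek-to and keep-in-group simultaneously.  An uninformed agent's
#' selection never references any target.
#'
#' @param informed Logical: is the agent informed (has a target)?
#' @param in_group Logical group status from [assess_status()].
#' @param policy `"strict_flowchart"` (default) or `"blend"`.
#' @return Character vector of behaviour identifiers; the last element is
#'   always `"crowd_repulsion"`.
#' @export
select_behaviours <- function(informed, in_group,
                              policy = c("strict_flowchart", "blend")) {
  policy <- match.arg(policy)
  active <- if (informed) {
    if (in_group) {
      "seek_to"
    } else if (policy == "blend") {
      c("seek_to", "keep_in_group")
    } else {
      "keep_in_group"
    }
  } else {
    if (in_group) "wander" else "keep_in_group"
  }
  c(active, "crowd_repulsion")
}
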