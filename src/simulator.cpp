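#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <queue>
#include <random>
#include <vector>

using namespace Rcpp;

// ----------------------------------------------------------------------------
// Random number stream.  One 64-bit Mersenne Twister per replicate: every
// stochastic draw (binding times, residence times, move outcomes, candidate
// positions) comes from this single stream, so a replicate is fully
// determined by its integer seed.
// ----------------------------------------------------------------------------
struct Rng {
    std::mt19937_64 eng;
    std::uniform_real_distribution<double> unif{0.0, 1.0};
    explicit Rng(uint64_t seed) : eng(seed) {}
    double runif() { return unif(eng); }
    // exponential with the given mean; guards against log(0)
    double rexp(double mean) {
        double u;
        do { u = unif(eng); } while (u <= 0.0);
        return -std::log(u) * mean;
    }
    // uniform integer on 0 .. n-1
    int runifInt(int n) {
        std::uniform_int_distribution<int> d(0, n - 1);
        return d(eng);
    }
};

// ----------------------------------------------------------------------------
// Species-level kinetic/geometric parameters (0-based positions throughout).
// ----------------------------------------------------------------------------
struct Species {
    int footprint;
    double kAssoc;
    double pLeft, pRight, pHop, pUnbind;
    int hopRange;
    bool mobile;
    bool cognate;
    std::vector<double> residence;  // mean residence per left-aligned
                                    // position, or length 1 for a flat
                                    // landscape
    int nPos;                       // number of left-aligned binding positions
    double meanRes(int pos) const {
        return residence.size() == 1 ? residence[0] : residence[pos];
    }
};

// move outcome codes
enum MoveOutcome { MOVE_LEFT = 0, MOVE_RIGHT = 1, MOVE_HOP = 2, MOVE_UNBIND = 3 };

static int drawMove(const Species& sp, Rng& rng) {
    double u = rng.runif();
    if (u < sp.pLeft) return MOVE_LEFT;
    if (u < sp.pLeft + sp.pRight) return MOVE_RIGHT;
    if (u < sp.pLeft + sp.pRight + sp.pHop) return MOVE_HOP;
    return MOVE_UNBIND;
}

// is the footprint window starting at `start` fully vacant?
static bool windowFree(const std::vector<uint8_t>& occ, int L, bool circular,
                       int start, int f) {
    if (circular) {
        for (int j = 0; j < f; ++j)
            if (occ[(start + j) % L]) return false;
    } else {
        if (start < 0 || start + f > L) return false;
        for (int j = 0; j < f; ++j)
            if (occ[start + j]) return false;
    }
    return true;
}

static void markWindow(std::vector<uint8_t>& occ, int L, bool circular,
                       int start, int f, uint8_t val) {
    if (circular) {
        for (int j = 0; j < f; ++j) occ[(start + j) % L] = val;
    } else {
        for (int j = 0; j < f; ++j) occ[start + j] = val;
    }
}

// ----------------------------------------------------------------------------
// Event queue: each molecule owns at most one pending event (a binding
// attempt when free, a residence expiry when bound).  Rescheduling bumps the
// molecule's version counter; stale heap entries are discarded lazily.
// ----------------------------------------------------------------------------
struct Ev {
    double t;
    int mol;
    uint64_t ver;
};
struct EvCmp {
    bool operator()(const Ev& a, const Ev& b) const { return a.t > b.t; }
};

struct Simulator {
    int L;
    bool circular;
    int target;  // left-aligned target position, 0-based (-1: none)
    double duration;
    bool stopAtFP;
    double burnin;
    bool audit;
    int maxIntervals;
    bool trackPositions;

    std::vector<Species> species;

    // per-molecule state
    std::vector<int> spOf;
    std::vector<uint8_t> bound;
    std::vector<int> pos;
    std::vector<uint64_t> version;

    std::vector<uint8_t> occ;
    long covered = 0;

    std::priority_queue<Ev, std::vector<Ev>, EvCmp> pq;
    Rng rng;

    // observables
    double tCur = 0.0;
    double covTimeInt = 0.0;   // integral of covered bp over time (post burn-in)
    double statTime = 0.0;     // time accumulated post burn-in
    std::vector<double> boundTimeInt;  // per species, post burn-in
    std::vector<long> boundCount;      // per species, current
    std::vector<long> nBind, nUnbind;  // per species, successful transitions
    int cogAtTarget = 0;
    double firstPassage = -1.0;
    double targetTime = 0.0;   // total time target occupied (no burn-in)
    double intervalOpen = -1.0;
    std::vector<double> ivOn, ivOff;
    std::vector<double> posTime;  // time-at-position for molecule 0

    Simulator(int L_, bool circ, int target_, double dur, uint64_t seed)
        : L(L_), circular(circ), target(target_), duration(dur),
          occ(L_, 0), rng(seed) {}

    void schedule(int m, double t) {
        ++version[m];
        pq.push(Ev{t, m, version[m]});
    }

    void accumulate(double t0, double t1) {
        if (t1 <= t0) return;
        // target occupancy runs from time zero
        if (cogAtTarget > 0) targetTime += t1 - t0;
        if (trackPositions && !posTime.empty() && bound.size() > 0 && bound[0])
            posTime[pos[0]] += t1 - t0;
        // coverage and bound-state fractions start after the burn-in
        double a = std::max(t0, burnin), b = t1;
        if (b <= a) return;
        double dt = b - a;
        statTime += dt;
        covTimeInt += static_cast<double>(covered) * dt;
        for (size_t s = 0; s < species.size(); ++s)
            boundTimeInt[s] += static_cast<double>(boundCount[s]) * dt;
    }

    void targetEnter(double t) {
        if (cogAtTarget == 0) {
            if (firstPassage < 0) firstPassage = t;
            intervalOpen = t;
        }
        ++cogAtTarget;
    }

    void targetLeave(double t) {
        --cogAtTarget;
        if (cogAtTarget == 0 && intervalOpen >= 0) {
            if (static_cast<int>(ivOn.size()) < maxIntervals) {
                ivOn.push_back(intervalOpen);
                ivOff.push_back(t);
            }
            intervalOpen = -1.0;
        }
    }

    void bindAt(int m, int p, double t) {
        const Species& sp = species[spOf[m]];
        markWindow(occ, L, circular, p, sp.footprint, 1);
        covered += sp.footprint;
        bound[m] = 1;
        pos[m] = p;
        ++boundCount[spOf[m]];
        ++nBind[spOf[m]];
        if (sp.cognate && p == target) targetEnter(t);
    }

    void unbindFrom(int m, double t) {
        const Species& sp = species[spOf[m]];
        markWindow(occ, L, circular, pos[m], sp.footprint, 0);
        covered -= sp.footprint;
        bound[m] = 0;
        --boundCount[spOf[m]];
        ++nUnbind[spOf[m]];
        if (sp.cognate && pos[m] == target) targetLeave(t);
    }

    void handleFree(int m, double t) {
        const Species& sp = species[spOf[m]];
        int cand = rng.runifInt(sp.nPos);
        if (windowFree(occ, L, circular, cand, sp.footprint)) {
            bindAt(m, cand, t);
            schedule(m, t + rng.rexp(sp.meanRes(cand)));
        } else {
            // failed attempt: stay free, redraw the next binding time
            schedule(m, t + rng.rexp(1.0 / sp.kAssoc));
        }
    }

    void relocate(int m, int np, double t) {
        // molecule m moves from pos[m] to np (vacancy already established)
        const Species& sp = species[spOf[m]];
        bool wasTarget = sp.cognate && pos[m] == target;
        markWindow(occ, L, circular, np, sp.footprint, 1);
        pos[m] = np;
        if (sp.cognate) {
            if (wasTarget && np != target) targetLeave(t);
            else if (!wasTarget && np == target) targetEnter(t);
        }
    }

    void handleBound(int m, double t) {
        const Species& sp = species[spOf[m]];
        int p = pos[m];
        int f = sp.footprint;
        int outcome = drawMove(sp, rng);
        if (outcome == MOVE_LEFT || outcome == MOVE_RIGHT) {
            int dir = (outcome == MOVE_LEFT) ? -1 : +1;
            bool blocked = false;
            int np = p;
            if (circular) {
                np = (p + dir + L) % L;
                // the single base pair newly covered by the shift
                int enter = (dir < 0) ? np : (p + f) % L;
                blocked = occ[enter] != 0;
            } else {
                if ((dir < 0 && p == 0) || (dir > 0 && p + f >= L)) {
                    blocked = true;  // genome end
                } else {
                    np = p + dir;
                    int enter = (dir < 0) ? np : p + f;
                    blocked = occ[enter] != 0;
                }
            }
            if (!blocked) {
                // vacate the trailing base pair, claim the leading one
                markWindow(occ, L, circular, p, f, 0);
                relocate(m, np, t);
            }
            // blocked slides leave the molecule in place; either way a fresh
            // residence time is drawn at the (possibly new) position
            schedule(m, t + rng.rexp(sp.meanRes(pos[m])));
        } else if (outcome == MOVE_HOP) {
            int d = 1 + rng.runifInt(sp.hopRange);
            if (rng.runifInt(2) == 0) d = -d;
            bool offEnd = false;
            int np = 0;
            if (circular) {
                np = ((p + d) % L + L) % L;
            } else {
                np = p + d;
                offEnd = (np < 0 || np + f > L);
            }
            // self-exclusion: vacate own footprint before the clash check
            markWindow(occ, L, circular, p, f, 0);
            if (!offEnd && windowFree(occ, L, circular, np, f)) {
                relocate(m, np, t);
                schedule(m, t + rng.rexp(sp.meanRes(np)));
            } else {
                // steric clash (or hop beyond a linear end): micro-dissociation
                covered -= f;
                bound[m] = 0;
                --boundCount[spOf[m]];
                ++nUnbind[spOf[m]];
                if (sp.cognate && p == target) targetLeave(t);
                schedule(m, t + rng.rexp(1.0 / sp.kAssoc));
            }
        } else {  // MOVE_UNBIND
            unbindFrom(m, t);
            schedule(m, t + rng.rexp(1.0 / species[spOf[m]].kAssoc));
        }
    }

    void auditState() const {
        std::vector<uint8_t> chk(L, 0);
        long cov = 0;
        for (size_t m = 0; m < bound.size(); ++m) {
            if (!bound[m]) continue;
            int f = species[spOf[m]].footprint;
            for (int j = 0; j < f; ++j) {
                int cell = circular ? (pos[m] + j) % L : pos[m] + j;
                if (chk[cell])
                    stop("steric violation: two footprints share base pair %d",
                         cell);
                chk[cell] = 1;
            }
            cov += f;
        }
        if (cov != covered) stop("internal error: coverage counter drift");
        for (int i = 0; i < L; ++i)
            if (chk[i] != occ[i])
                stop("internal error: occupancy index out of sync at %d", i);
    }

    void run() {
        while (!pq.empty()) {
            Ev e = pq.top();
            pq.pop();
            if (e.ver != version[e.mol]) continue;  // stale entry
            if (e.t < tCur - 1e-9)
                stop("internal error: event-time regression (%.6g < %.6g)",
                     e.t, tCur);
            if (e.t >= duration) break;
            accumulate(tCur, e.t);
            tCur = e.t;
            if (bound[e.mol]) handleBound(e.mol, tCur);
            else handleFree(e.mol, tCur);
            if (audit) auditState();
            if (stopAtFP && firstPassage >= 0) break;
        }
        bool stoppedEarly = stopAtFP && firstPassage >= 0;
        if (!stoppedEarly && duration > tCur) {
            accumulate(tCur, duration);
            tCur = duration;
        }
        if (intervalOpen >= 0) {  // close the trailing occupancy interval
            if (static_cast<int>(ivOn.size()) < maxIntervals) {
                ivOn.push_back(intervalOpen);
                ivOff.push_back(tCur);
            }
            intervalOpen = -1.0;
        }
    }
};

// ----------------------------------------------------------------------------
// Entry point.  `speciesList` carries one list per species with elements
// footprint, k_assoc, move_probs (left, right, hop, unbind), hop_range,
// mobile, cognate, residence (length nPos or 1), n_pos, copy_number,
// initial_positions (0-based, possibly empty).
// ----------------------------------------------------------------------------
// [[Rcpp::export(name = ".cppRunSimulation")]]
List cppRunSimulation(int L, bool circular, int targetStart, List speciesList,
                      double duration, double seed, bool stopAtFirstPassage,
                      double burnin, bool audit, int maxIntervals,
                      bool trackPositions, int maxPlacementTries) {
    Simulator sim(L, circular, targetStart, duration,
                  static_cast<uint64_t>(seed));
    sim.stopAtFP = stopAtFirstPassage;
    sim.burnin = burnin;
    sim.audit = audit;
    sim.maxIntervals = maxIntervals;
    sim.trackPositions = trackPositions;

    int nSpecies = speciesList.size();
    std::vector<int> copyNum(nSpecies);
    std::vector<std::vector<int>> initPos(nSpecies);
    for (int s = 0; s < nSpecies; ++s) {
        List sl = speciesList[s];
        Species sp;
        sp.footprint = as<int>(sl["footprint"]);
        sp.kAssoc = as<double>(sl["k_assoc"]);
        NumericVector mp = sl["move_probs"];
        sp.pLeft = mp[0];
        sp.pRight = mp[1];
        sp.pHop = mp[2];
        sp.pUnbind = mp[3];
        sp.hopRange = as<int>(sl["hop_range"]);
        sp.mobile = as<bool>(sl["mobile"]);
        sp.cognate = as<bool>(sl["cognate"]);
        NumericVector res = sl["residence"];
        sp.residence.assign(res.begin(), res.end());
        sp.nPos = as<int>(sl["n_pos"]);
        sim.species.push_back(sp);
        copyNum[s] = as<int>(sl["copy_number"]);
        IntegerVector ip = sl["initial_positions"];
        initPos[s].assign(ip.begin(), ip.end());
    }

    int nMol = 0;
    for (int s = 0; s < nSpecies; ++s) nMol += copyNum[s];
    sim.spOf.resize(nMol);
    sim.bound.assign(nMol, 0);
    sim.pos.assign(nMol, -1);
    sim.version.assign(nMol, 0);
    sim.boundTimeInt.assign(nSpecies, 0.0);
    sim.boundCount.assign(nSpecies, 0);
    sim.nBind.assign(nSpecies, 0);
    sim.nUnbind.assign(nSpecies, 0);
    if (trackPositions) sim.posTime.assign(L, 0.0);

    std::vector<std::vector<int>> immobileInit(nSpecies);

    int m0 = 0;
    for (int s = 0; s < nSpecies; ++s) {
        const Species& sp = sim.species[s];
        for (int i = 0; i < copyNum[s]; ++i) {
            int m = m0 + i;
            sim.spOf[m] = s;
            bool placed = false;
            if (i < static_cast<int>(initPos[s].size())) {
                int p = initPos[s][i];
                if (p < 0 || p >= sp.nPos)
                    stop("initial position %d out of range for species %d",
                         p + 1, s + 1);
                if (!windowFree(sim.occ, L, circular, p, sp.footprint))
                    stop("initial position %d clashes with an earlier "
                         "placement", p + 1);
                sim.bindAt(m, p, 0.0);
                --sim.nBind[s];  // initial placement is not a binding event
                placed = true;
            } else if (!sp.mobile) {
                // immobile obstacles: uniform random non-overlapping start
                // positions via rejection sampling
                int tries = 0;
                while (tries < maxPlacementTries) {
                    int cand = sim.rng.runifInt(sp.nPos);
                    if (windowFree(sim.occ, L, circular, cand, sp.footprint)) {
                        sim.bindAt(m, cand, 0.0);
                        --sim.nBind[s];
                        placed = true;
                        break;
                    }
                    ++tries;
                }
                if (!placed)
                    stop("could not place immobile molecule %d of species %d "
                         "after %d tries (achieved coverage %.1f%%)",
                         i + 1, s + 1, maxPlacementTries,
                         100.0 * sim.covered / L);
            }
            if (placed) {
                if (sp.mobile)
                    sim.schedule(m, sim.rng.rexp(sp.meanRes(sim.pos[m])));
                // immobile molecules never receive events
                if (!sp.mobile) immobileInit[s].push_back(sim.pos[m]);
            } else {
                // mobile molecules start free with an exponential binding time
                sim.schedule(m, sim.rng.rexp(1.0 / sp.kAssoc));
            }
        }
        m0 += copyNum[s];
    }
    if (audit) sim.auditState();

    sim.run();

    // assemble results
    double statT = sim.statTime;
    NumericVector boundFrac(nSpecies), bindN(nSpecies), unbindN(nSpecies);
    for (int s = 0; s < nSpecies; ++s) {
        boundFrac[s] = (statT > 0 && copyNum[s] > 0)
                           ? sim.boundTimeInt[s] / (statT * copyNum[s])
                           : NA_REAL;
        bindN[s] = static_cast<double>(sim.nBind[s]);
        unbindN[s] = static_cast<double>(sim.nUnbind[s]);
    }
    double meanCov = statT > 0 ? sim.covTimeInt / (statT * L)
                               : static_cast<double>(sim.covered) / L;
    int nIv = static_cast<int>(sim.ivOn.size());
    NumericMatrix intervals(nIv, 2);
    for (int i = 0; i < nIv; ++i) {
        intervals(i, 0) = sim.ivOn[i];
        intervals(i, 1) = sim.ivOff[i];
    }
    List immList(nSpecies), finalPos(nSpecies), freeCount(nSpecies);
    m0 = 0;
    for (int s = 0; s < nSpecies; ++s) {
        IntegerVector iv(immobileInit[s].begin(), immobileInit[s].end());
        immList[s] = iv;
        std::vector<int> fp;
        int nFree = 0;
        for (int i = 0; i < copyNum[s]; ++i) {
            if (sim.bound[m0 + i]) fp.push_back(sim.pos[m0 + i]);
            else ++nFree;
        }
        finalPos[s] = IntegerVector(fp.begin(), fp.end());
        freeCount[s] = nFree;
        m0 += copyNum[s];
    }

    List out = List::create(
        _["first_passage"] = sim.firstPassage >= 0 ? sim.firstPassage : NA_REAL,
        _["censored"] = sim.firstPassage < 0,
        _["occupancy_time"] = sim.targetTime,
        _["occupancy_fraction"] = duration > 0 ? sim.targetTime / duration : 0.0,
        _["mean_coverage"] = meanCov,
        _["bound_fraction"] = boundFrac,
        _["n_bind"] = bindN,
        _["n_unbind"] = unbindN,
        _["intervals"] = intervals,
        _["immobile_positions"] = immList,
        _["final_positions"] = finalPos,
        _["n_free"] = freeCount,
        _["time_simulated"] = sim.tCur,
        _["stat_time"] = statT);
    if (trackPositions)
        out["position_time"] = NumericVector(sim.posTime.begin(),
                                             sim.posTime.end());
    return out;
}

// ----------------------------------------------------------------------------
// Small exported helpers that reuse the simulator's code paths, so unit
// tests can probe single operations against independent oracles.
// ----------------------------------------------------------------------------

// Draw `n` move outcomes with the categorical rule used by the simulator.
// Returns counts of (slide left, slide right, hop, unbind).
// [[Rcpp::export(name = ".cppMoveOutcomes")]]
IntegerVector cppMoveOutcomes(NumericVector moveProbs, int n, double seed) {
    Species sp;
    sp.pLeft = moveProbs[0];
    sp.pRight = moveProbs[1];
    sp.pHop = moveProbs[2];
    sp.pUnbind = moveProbs[3];
    Rng rng(static_cast<uint64_t>(seed));
    IntegerVector counts(4);
    for (int i = 0; i < n; ++i) counts[drawMove(sp, rng)]++;
    return counts;
}

// Repeated binding attempts against a fixed occupancy pattern; returns the
// number of accepted placements out of `trials` uniform candidate draws.
// [[Rcpp::export(name = ".cppBindAcceptance")]]
int cppBindAcceptance(IntegerVector occupied, bool circular, int footprint,
                      int trials, double seed) {
    int L = occupied.size();
    std::vector<uint8_t> occ(occupied.begin(), occupied.end());
    int nPos = circular ? L : L - footprint + 1;
    Rng rng(static_cast<uint64_t>(seed));
    int acc = 0;
    for (int i = 0; i < trials; ++i) {
        int cand = rng.runifInt(nPos);
        if (windowFree(occ, L, circular, cand, footprint)) ++acc;
    }
    return acc;
}
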