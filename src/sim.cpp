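#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Multi-round driver for the threshold public-goods game with punishment.
//
// Replays exactly the runif draw sequence of the pure-R engine
// (partition keys, partner draws, adoption coins, mutation keys, mutation
// targets), so for a given seed the two engines are bit-identical.  All
// randomness goes through unif_rand() on R's own RNG stream.

static const double EPS = 1e-9;

static void argsort(const std::vector<double>& key, std::vector<int>& idx) {
    std::iota(idx.begin(), idx.end(), 0);
    std::stable_sort(idx.begin(), idx.end(),
                     [&key](int i, int j) { return key[i] < key[j]; });
}

// [[Rcpp::export]]
List sim_run_cpp(List par, IntegerVector init_strat) {
    const int N = as<int>(par["N"]);
    const int a = as<int>(par["a"]);
    const int n = as<int>(par["n"]);
    const double m = as<double>(par["m"]);
    const double u = as<double>(par["u"]);
    const double w1 = as<double>(par["w1"]);
    const double w = as<double>(par["w"]);
    const double w2 = as<double>(par["w2"]);
    const double t1 = as<double>(par["t1"]);
    const double t2 = as<double>(par["t2"]);
    const double U = as<double>(par["U"]);
    const double beta = as<double>(par["beta"]);
    const int T = as<int>(par["rounds"]);
    const int mut_k = as<int>(par["mut_k"]);
    const bool subgroup_scope = as<bool>(par["subgroup_scope"]);
    const bool keep_debts = as<bool>(par["keep_debts"]);
    const bool cumulative = as<bool>(par["cumulative"]);
    const bool one_act = as<bool>(par["peer_one_act"]);
    const IntegerVector set = par["strategy_set"];   // sorted codes 1..4
    const int ns = set.size();

    std::vector<int> strat(init_strat.begin(), init_strat.end());
    std::vector<int> next_strat(N), group_of(N), perm(N), ord(N);
    std::vector<double> key(N), res(N), wealth(N, 0.0), up(N), uc(N),
        un(mut_k > 0 ? mut_k : 1);

    IntegerMatrix counts(T, 4);
    IntegerVector successes(T), succ_collab(T);
    NumericMatrix ledger(T, 4);  // central_loss, central_cost, peer_loss, peer_cost

    GetRNGstate();
    for (int r = 0; r < T; ++r) {
        for (int i = 0; i < N; ++i) counts(r, strat[i] - 1)++;

        // random partition: permutation = argsort of N uniform keys
        for (int i = 0; i < N; ++i) key[i] = unif_rand();
        argsort(key, perm);

        int succ = 0, scol = 0;
        double cl = 0, cc = 0, pl = 0, pc = 0;
        for (int g = 0; g < a; ++g) {
            const int* blk = perm.data() + g * n;
            int nC = 0, nCP = 0, nPP = 0, nD = 0;
            for (int j = 0; j < n; ++j) {
                group_of[blk[j]] = g;
                switch (strat[blk[j]]) {
                    case 1: nC++; break;
                    case 2: nCP++; break;
                    case 3: nPP++; break;
                    default: nD++;
                }
            }
            const double total = u * (nC + nCP + nPP);
            const bool inst = w1 * nCP >= w - EPS;
            const bool success = total >= U - EPS;
            cc += w1 * nCP;
            if (inst) cl += t1 * nD;
            // pairwise: every PP punishes every D (cost w2 per pair);
            // one_act: each PP performs one punishment act per round, its
            // t2 effect spread over the subgroup's defectors
            const double acts = one_act ? (nD > 0 ? nPP : 0) : nPP * nD;
            pl += t2 * acts;
            pc += w2 * acts;
            if (success) { succ++; scol += nC + nCP + nPP; }
            for (int j = 0; j < n; ++j) {
                const int i = blk[j];
                double b = m;
                const int s = strat[i];
                if (s != 4) b -= u;
                if (s == 2) b -= w1;
                if (s == 3) b -= one_act ? (nD > 0 ? w2 : 0.0) : w2 * nD;
                if (s == 4) b -= (inst ? t1 : 0.0) +
                    (one_act ? t2 * nPP / nD : t2 * nPP);
                // failed subgroup loses everything; under "debts" failure
                // zeroes only what a member holds, punishment debts persist
                res[i] = success ? b : (keep_debts && b < 0 ? b : 0.0);
                // accumulated holdings: grow on success, wiped on failure
                wealth[i] = success ? wealth[i] + b
                                    : (keep_debts ? std::min(wealth[i] + b, 0.0)
                                                  : 0.0);
            }
        }
        successes[r] = succ;
        succ_collab[r] = scol;
        ledger(r, 0) = cl; ledger(r, 1) = cc;
        ledger(r, 2) = pl; ledger(r, 3) = pc;

        // synchronous Fermi imitation against the frozen snapshot
        for (int i = 0; i < N; ++i) up[i] = unif_rand();
        for (int i = 0; i < N; ++i) uc[i] = unif_rand();
        for (int i = 0; i < N; ++i) {
            int j;
            if (subgroup_scope) {
                const int* blk = perm.data() + group_of[i] * n;
                int pick = (int)std::floor(up[i] * (n - 1));
                if (pick > n - 2) pick = n - 2;
                j = -1;
                for (int t = 0, seen = 0; t < n; ++t) {
                    if (blk[t] == i) continue;
                    if (seen++ == pick) { j = blk[t]; break; }
                }
            } else {
                long j0 = (long)std::floor(up[i] * (N - 1));
                if (j0 > N - 2) j0 = N - 2;
                if (j0 >= i) j0++;
                j = (int)j0;
            }
            const double ri = cumulative ? wealth[i] : res[i];
            const double rj = cumulative ? wealth[j] : res[j];
            const double pij = 1.0 / (1.0 + std::exp((ri - rj) / beta));
            next_strat[i] = (uc[i] < pij) ? strat[j] : strat[i];
        }
        std::swap(strat, next_strat);

        // mutation: round(alpha*N) distinct individuals resample their strategy
        if (mut_k > 0) {
            for (int i = 0; i < N; ++i) key[i] = unif_rand();
            argsort(key, ord);
            for (int t = 0; t < mut_k; ++t) un[t] = unif_rand();
            for (int t = 0; t < mut_k; ++t) {
                const int i = ord[t];
                int pick = (int)std::floor(un[t] * (ns - 1));
                if (pick > ns - 2) pick = ns - 2;
                for (int s = 0, seen = 0; s < ns; ++s) {
                    if (set[s] == strat[i]) continue;
                    if (seen++ == pick) { strat[i] = set[s]; break; }
                }
            }
        }
    }
    PutRNGstate();

    return List::create(
        _["counts"] = counts,
        _["successes"] = successes,
        _["succ_collaborators"] = succ_collab,
        _["ledger"] = ledger,
        _["final_strategies"] = IntegerVector(strat.begin(), strat.end()),
        _["final_resources"] = NumericVector(res.begin(), res.end()));
}
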