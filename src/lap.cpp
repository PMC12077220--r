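#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

// Dense linear assignment by shortest augmenting paths with dual updates
// (Jonker-Volgenant / Crouse style). Rectangular cost matrices with
// nrow <= ncol; every row is assigned to a distinct column. Infeasible
// pairs should carry a large finite cost so the problem stays feasible.

static int augmenting_path(int nc, const std::vector<double> &cost,
                           std::vector<double> &u, std::vector<double> &v,
                           std::vector<int> &path, const std::vector<int> &row4col,
                           std::vector<double> &shortestPathCosts, int i,
                           std::vector<bool> &SR, std::vector<bool> &SC,
                           std::vector<int> &remaining, double *p_minVal)
{
    const double INF = std::numeric_limits<double>::infinity();
    double minVal = 0;
    int num_remaining = nc;
    for (int it = 0; it < nc; it++)
        remaining[it] = nc - it - 1;
    std::fill(SR.begin(), SR.end(), false);
    std::fill(SC.begin(), SC.end(), false);
    std::fill(shortestPathCosts.begin(), shortestPathCosts.end(), INF);

    int sink = -1;
    while (sink == -1) {
        int index = -1;
        double lowest = INF;
        SR[i] = true;
        for (int it = 0; it < num_remaining; it++) {
            int j = remaining[it];
            double r = minVal + cost[(size_t)i * nc + j] - u[i] - v[j];
            if (r < shortestPathCosts[j]) {
                path[j] = i;
                shortestPathCosts[j] = r;
            }
            // prefer unassigned columns on ties so the path terminates sooner
            if (shortestPathCosts[j] < lowest ||
                (shortestPathCosts[j] == lowest && row4col[j] == -1)) {
                lowest = shortestPathCosts[j];
                index = it;
            }
        }
        minVal = lowest;
        if (minVal == INF)
            return -1;
        int j = remaining[index];
        if (row4col[j] == -1)
            sink = j;
        else
            i = row4col[j];
        SC[j] = true;
        remaining[index] = remaining[--num_remaining];
    }
    *p_minVal = minVal;
    return sink;
}

// [[Rcpp::export(name = ".lap_solve")]]
Rcpp::IntegerVector lap_solve(Rcpp::NumericMatrix costm)
{
    int nr = costm.nrow(), nc = costm.ncol();
    if (nr == 0)
        return Rcpp::IntegerVector(0);
    if (nr > nc)
        Rcpp::stop("cost matrix must have nrow <= ncol");
    // row-major copy
    std::vector<double> cost((size_t)nr * nc);
    for (int i = 0; i < nr; i++)
        for (int j = 0; j < nc; j++) {
            double cval = costm(i, j);
            if (!R_FINITE(cval))
                Rcpp::stop("cost matrix entries must be finite");
            cost[(size_t)i * nc + j] = cval;
        }

    std::vector<double> u(nr, 0.0), v(nc, 0.0), shortestPathCosts(nc);
    std::vector<int> path(nc, -1), col4row(nr, -1), row4col(nc, -1), remaining(nc);
    std::vector<bool> SR(nr), SC(nc);

    for (int curRow = 0; curRow < nr; curRow++) {
        double minVal;
        int sink = augmenting_path(nc, cost, u, v, path, row4col,
                                   shortestPathCosts, curRow, SR, SC,
                                   remaining, &minVal);
        if (sink < 0)
            Rcpp::stop("assignment infeasible");
        u[curRow] += minVal;
        for (int i = 0; i < nr; i++)
            if (SR[i] && i != curRow)
                u[i] += minVal - shortestPathCosts[col4row[i]];
        for (int j = 0; j < nc; j++)
            if (SC[j])
                v[j] -= minVal - shortestPathCosts[j];
        // augment along the alternating path back to curRow
        int j = sink;
        while (true) {
            int i = path[j];
            row4col[j] = i;
            std::swap(col4row[i], j);
            if (i == curRow)
                break;
        }
    }

    Rcpp::IntegerVector out(nr);
    for (int i = 0; i < nr; i++)
        out[i] = col4row[i] + 1; // 1-based for R
    return out;
}
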