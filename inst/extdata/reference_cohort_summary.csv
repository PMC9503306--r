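group,radius_px,metric,mean,sd
1a,4,fd_percent,36.76,1.42
1a,4,fd_mean_size_um2,975.13,117.83
1a,4,fd_total_area_mm2,14.70,1.29
1a,4,fd_count,13639.5,1120.76
1b,4,fd_percent,48.96,7.63
1b,4,fd_mean_size_um2,9415.08,14453.98
1b,4,fd_total_area_mm2,17.62,2.74
1b,4,fd_count,5221.14,4123.72
2,4,fd_percent,45.61,3.98
2,4,fd_mean_size_um2,3321.92,1942.51
2,4,fd_total_area_mm2,16.42,1.43
2,4,fd_count,7085.5,2965.60
1a,8,fd_percent,41.47,1.40
1a,8,fd_mean_size_um2,1157.83,140.24
1a,8,fd_total_area_mm2,13.50,0.50
1a,8,fd_count,11721,982.87
1b,8,fd_percent,49.41,7.42
1b,8,fd_mean_size_um2,8279.53,10091.57
1b,8,fd_total_area_mm2,17.78,2.67
1b,8,fd_count,4719.85,3405.69
2,8,fd_percent,46.07,1.40
2,8,fd_mean_size_um2,3551.65,1895.34
2,8,fd_total_area_mm2,16.58,1.39
2,8,fd_count,5324,2449.41
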