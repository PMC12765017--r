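type	SBS1_like	SBS5_like	SBS26_like
A[C>A]A	0.001241	0.014402	0.001996
A[C>A]C	0.001242	0.014629	0.002433
A[C>A]G	0.001129	0.008003	0.002981
A[C>A]T	0.001092	0.013543	0.002682
C[C>A]A	0.002037	0.011622	0.002699
C[C>A]C	0.001208	0.010374	0.001719
C[C>A]G	0.002454	0.012588	0.001717
C[C>A]T	0.00243	0.006461	0.00213
G[C>A]A	0.002734	0.011778	0.003457
G[C>A]C	0.002007	0.012267	0.003505
G[C>A]G	0.002668	0.009749	0.002971
G[C>A]T	0.001861	0.01241	0.002955
T[C>A]A	0.001298	0.014604	0.002482
T[C>A]C	0.00186	0.00769	0.001204
T[C>A]G	0.002897	0.009796	0.002658
T[C>A]T	0.001943	0.014659	0.003204
A[C>G]A	0.001485	0.015048	0.002999
A[C>G]C	0.001499	0.006286	0.002283
A[C>G]G	0.002057	0.009925	0.002482
A[C>G]T	0.002269	0.010794	0.002486
C[C>G]A	0.001651	0.014292	0.001202
C[C>G]C	0.001107	0.006502	0.002051
C[C>G]G	0.001878	0.015156	0.002665
C[C>G]T	0.002642	0.014726	0.003185
G[C>G]A	0.002121	0.005929	0.002053
G[C>G]C	0.001684	0.010324	0.002182
G[C>G]G	0.002067	0.009062	0.002573
G[C>G]T	0.002749	0.01431	0.002611
T[C>G]A	0.001954	0.00964	0.002923
T[C>G]C	0.001326	0.0136	0.002145
T[C>G]G	0.002059	0.012598	0.003401
T[C>G]T	0.002884	0.013346	0.003505
A[C>T]A	0.001606	0.009041	0.013184
A[C>T]C	0.002606	0.012064	0.022009
A[C>T]G	0.159286	0.00513	0.025229
A[C>T]T	0.001353	0.013568	0.019834
C[C>T]A	0.001082	0.005164	0.020338
C[C>T]C	0.001472	0.007204	0.025835
C[C>T]G	0.167981	0.014319	0.024273
C[C>T]T	0.001301	0.011317	0.019409
G[C>T]A	0.001587	0.008953	0.023751
G[C>T]C	0.001021	0.009526	0.011031
G[C>T]G	0.29537	0.005471	0.022728
G[C>T]T	0.002574	0.015	0.020196
T[C>T]A	0.001158	0.009485	0.011655
T[C>T]C	0.002704	0.014837	0.01043
T[C>T]G	0.208141	0.014127	0.017328
T[C>T]T	0.001818	0.011604	0.022995
A[T>A]A	0.00112	0.014974	0.002956
A[T>A]C	0.002095	0.011389	0.003157
A[T>A]G	0.001126	0.008484	0.001606
A[T>A]T	0.001404	0.008619	0.003462
C[T>A]A	0.002072	0.009146	0.001902
C[T>A]C	0.001938	0.013078	0.001556
C[T>A]G	0.001302	0.005486	0.002922
C[T>A]T	0.001282	0.012712	0.001975
G[T>A]A	0.001972	0.011984	0.003065
G[T>A]C	0.002843	0.006833	0.002144
G[T>A]G	0.001646	0.007747	0.002825
G[T>A]T	0.001359	0.010326	0.003058
T[T>A]A	0.001519	0.011967	0.001648
T[T>A]C	0.002034	0.015094	0.001268
T[T>A]G	0.001029	0.012822	0.001523
T[T>A]T	0.002563	0.010856	0.002828
A[T>C]A	0.001205	0.013739	0.051579
A[T>C]C	0.002052	0.007019	0.037763
A[T>C]G	0.002114	0.007851	0.039606
A[T>C]T	0.002208	0.01352	0.025055
C[T>C]A	0.002398	0.012146	0.037214
C[T>C]C	0.00123	0.007538	0.024428
C[T>C]G	0.001601	0.005527	0.034218
C[T>C]T	0.002853	0.00652	0.029371
G[T>C]A	0.001974	0.007292	0.02215
G[T>C]C	0.001254	0.00997	0.024664
G[T>C]G	0.002702	0.007099	0.044206
G[T>C]T	0.001392	0.012412	0.03278
T[T>C]A	0.002813	0.00517	0.032858
T[T>C]C	0.002737	0.008912	0.03524
T[T>C]G	0.001256	0.010326	0.033341
T[T>C]T	0.002537	0.005106	0.02288
A[T>G]A	0.001882	0.01101	0.003175
A[T>G]C	0.001255	0.006697	0.002618
A[T>G]G	0.002734	0.008744	0.003102
A[T>G]T	0.001651	0.011662	0.003041
C[T>G]A	0.001617	0.012987	0.003398
C[T>G]C	0.001784	0.010827	0.003266
C[T>G]G	0.001932	0.007469	0.001958
C[T>G]T	0.001713	0.006006	0.00182
G[T>G]A	0.001906	0.005961	0.002977
G[T>G]C	0.001085	0.008197	0.002989
G[T>G]G	0.001357	0.011884	0.003398
G[T>G]T	0.002926	0.005092	0.003099
T[T>G]A	0.001635	0.007213	0.001518
T[T>G]C	0.001324	0.014588	0.001888
T[T>G]G	0.00195	0.014512	0.001665
T[T>G]T	0.001024	0.012562	0.003077
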