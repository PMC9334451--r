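subject,session,has_snellen,has_reading_test,has_video,position
1,1,TRUE,FALSE,FALSE,NA
1,2,FALSE,TRUE,TRUE,1
1,3,FALSE,FALSE,TRUE,NA
1,4,FALSE,FALSE,TRUE,NA
1,5,FALSE,TRUE,TRUE,2
1,6,FALSE,FALSE,TRUE,NA
1,7,FALSE,FALSE,TRUE,NA
1,8,FALSE,FALSE,TRUE,NA
1,9,FALSE,FALSE,TRUE,NA
1,10,FALSE,FALSE,TRUE,NA
1,11,FALSE,TRUE,TRUE,4
1,12,FALSE,FALSE,TRUE,NA
1,13,FALSE,FALSE,TRUE,NA
1,14,FALSE,TRUE,TRUE,5
1,15,FALSE,FALSE,TRUE,NA
1,16,FALSE,FALSE,TRUE,NA
1,17,FALSE,FALSE,TRUE,NA
1,18,FALSE,FALSE,TRUE,NA
1,19,FALSE,FALSE,TRUE,NA
1,20,FALSE,TRUE,TRUE,7
1,21,FALSE,FALSE,TRUE,NA
1,22,FALSE,FALSE,TRUE,NA
1,23,FALSE,TRUE,FALSE,8
2,1,TRUE,FALSE,FALSE,NA
2,2,FALSE,TRUE,TRUE,1
2,3,FALSE,FALSE,TRUE,NA
2,4,FALSE,FALSE,TRUE,NA
2,5,FALSE,FALSE,TRUE,NA
2,6,FALSE,FALSE,TRUE,NA
2,7,FALSE,FALSE,TRUE,NA
2,8,FALSE,TRUE,TRUE,3
2,9,FALSE,FALSE,TRUE,NA
2,10,FALSE,FALSE,TRUE,NA
2,11,FALSE,FALSE,TRUE,NA
2,12,FALSE,FALSE,TRUE,NA
2,13,FALSE,FALSE,TRUE,NA
2,14,FALSE,TRUE,TRUE,5
2,15,FALSE,FALSE,TRUE,NA
2,16,FALSE,FALSE,TRUE,NA
2,17,FALSE,TRUE,TRUE,6
2,18,FALSE,FALSE,TRUE,NA
2,19,FALSE,FALSE,TRUE,NA
2,20,FALSE,TRUE,TRUE,7
2,21,FALSE,FALSE,TRUE,NA
2,22,FALSE,FALSE,TRUE,NA
2,23,FALSE,TRUE,FALSE,8
3,1,TRUE,FALSE,FALSE,NA
3,2,FALSE,TRUE,TRUE,1
3,3,FALSE,FALSE,TRUE,NA
3,4,FALSE,FALSE,TRUE,NA
3,5,FALSE,TRUE,TRUE,2
3,6,FALSE,FALSE,TRUE,NA
3,7,FALSE,FALSE,TRUE,NA
3,8,FALSE,FALSE,TRUE,NA
3,9,FALSE,FALSE,TRUE,NA
3,10,FALSE,FALSE,TRUE,NA
3,11,FALSE,TRUE,TRUE,4
3,12,FALSE,FALSE,TRUE,NA
3,13,FALSE,FALSE,TRUE,NA
3,14,FALSE,FALSE,TRUE,NA
3,15,FALSE,FALSE,TRUE,NA
3,16,FALSE,FALSE,TRUE,NA
3,17,FALSE,TRUE,TRUE,6
3,18,FALSE,FALSE,TRUE,NA
3,19,FALSE,FALSE,TRUE,NA
3,20,FALSE,TRUE,TRUE,7
3,21,FALSE,FALSE,TRUE,NA
3,22,FALSE,FALSE,TRUE,NA
3,23,FALSE,TRUE,FALSE,8
4,1,TRUE,FALSE,FALSE,NA
4,2,FALSE,TRUE,TRUE,1
4,3,FALSE,FALSE,TRUE,NA
4,4,FALSE,FALSE,TRUE,NA
4,5,FALSE,TRUE,TRUE,2
4,6,FALSE,FALSE,TRUE,NA
4,7,FALSE,FALSE,TRUE,NA
4,8,FALSE,TRUE,TRUE,3
4,9,FALSE,FALSE,TRUE,NA
4,10,FALSE,FALSE,TRUE,NA
4,11,FALSE,FALSE,TRUE,NA
4,12,FALSE,FALSE,TRUE,NA
4,13,FALSE,FALSE,TRUE,NA
4,14,FALSE,TRUE,TRUE,5
4,15,FALSE,FALSE,TRUE,NA
4,16,FALSE,FALSE,TRUE,NA
4,17,FALSE,FALSE,TRUE,NA
4,18,FALSE,FALSE,TRUE,NA
4,19,FALSE,FALSE,TRUE,NA
4,20,FALSE,TRUE,TRUE,7
4,21,FALSE,FALSE,TRUE,NA
4,22,FALSE,FALSE,TRUE,NA
4,23,FALSE,TRUE,FALSE,8
5,1,TRUE,FALSE,FALSE,NA
5,2,FALSE,TRUE,TRUE,1
5,3,FALSE,FALSE,TRUE,NA
5,4,FALSE,FALSE,TRUE,NA
5,5,FALSE,TRUE,TRUE,2
5,6,FALSE,FALSE,TRUE,NA
5,7,FALSE,FALSE,TRUE,NA
5,8,FALSE,TRUE,TRUE,3
5,9,FALSE,FALSE,TRUE,NA
5,10,FALSE,FALSE,TRUE,NA
5,11,FALSE,TRUE,TRUE,4
5,12,FALSE,FALSE,TRUE,NA
5,13,FALSE,FALSE,TRUE,NA
5,14,FALSE,FALSE,TRUE,NA
5,15,FALSE,FALSE,TRUE,NA
5,16,FALSE,FALSE,TRUE,NA
5,17,FALSE,TRUE,TRUE,6
5,18,FALSE,FALSE,TRUE,NA
5,19,FALSE,FALSE,TRUE,NA
5,20,FALSE,FALSE,TRUE,NA
5,21,FALSE,FALSE,TRUE,NA
5,22,FALSE,FALSE,TRUE,NA
5,23,FALSE,TRUE,FALSE,8
6,1,TRUE,FALSE,FALSE,NA
6,2,FALSE,TRUE,TRUE,1
6,3,FALSE,FALSE,TRUE,NA
6,4,FALSE,FALSE,TRUE,NA
6,5,FALSE,TRUE,TRUE,2
6,6,FALSE,FALSE,TRUE,NA
6,7,FALSE,FALSE,TRUE,NA
6,8,FALSE,TRUE,TRUE,3
6,9,FALSE,FALSE,TRUE,NA
6,10,FALSE,FALSE,TRUE,NA
6,11,FALSE,FALSE,TRUE,NA
6,12,FALSE,FALSE,TRUE,NA
6,13,FALSE,FALSE,TRUE,NA
6,14,FALSE,TRUE,TRUE,5
6,15,FALSE,FALSE,TRUE,NA
6,16,FALSE,FALSE,TRUE,NA
6,17,FALSE,TRUE,TRUE,6
6,18,FALSE,FALSE,TRUE,NA
6,19,FALSE,FALSE,TRUE,NA
6,20,FALSE,FALSE,TRUE,NA
6,21,FALSE,FALSE,TRUE,NA
6,22,FALSE,FALSE,TRUE,NA
6,23,FALSE,TRUE,FALSE,8
7,1,TRUE,FALSE,FALSE,NA
7,2,FALSE,TRUE,TRUE,1
7,3,FALSE,FALSE,TRUE,NA
7,4,FALSE,FALSE,TRUE,NA
7,5,FALSE,TRUE,TRUE,2
7,6,FALSE,FALSE,TRUE,NA
7,7,FALSE,FALSE,TRUE,NA
7,8,FALSE,FALSE,TRUE,NA
7,9,FALSE,FALSE,TRUE,NA
7,10,FALSE,FALSE,TRUE,NA
7,11,FALSE,TRUE,TRUE,4
7,12,FALSE,FALSE,TRUE,NA
7,13,FALSE,FALSE,TRUE,NA
7,14,FALSE,TRUE,TRUE,5
7,15,FALSE,FALSE,TRUE,NA
7,16,FALSE,FALSE,TRUE,NA
7,17,FALSE,TRUE,TRUE,6
7,18,FALSE,FALSE,TRUE,NA
7,19,FALSE,FALSE,TRUE,NA
7,20,FALSE,FALSE,TRUE,NA
7,21,FALSE,FALSE,TRUE,NA
7,22,FALSE,FALSE,TRUE,NA
7,23,FALSE,TRUE,FALSE,8
8,1,TRUE,FALSE,FALSE,NA
8,2,FALSE,TRUE,TRUE,1
8,3,FALSE,FALSE,TRUE,NA
8,4,FALSE,FALSE,TRUE,NA
8,5,FALSE,FALSE,TRUE,NA
8,6,FALSE,FALSE,TRUE,NA
8,7,FALSE,FALSE,TRUE,NA
8,8,FALSE,TRUE,TRUE,3
8,9,FALSE,FALSE,TRUE,NA
8,10,FALSE,FALSE,TRUE,NA
8,11,FALSE,TRUE,TRUE,4
8,12,FALSE,FALSE,TRUE,NA
8,13,FALSE,FALSE,TRUE,NA
8,14,FALSE,TRUE,TRUE,5
8,15,FALSE,FALSE,TRUE,NA
8,16,FALSE,FALSE,TRUE,NA
8,17,FALSE,FALSE,TRUE,NA
8,18,FALSE,FALSE,TRUE,NA
8,19,FALSE,FALSE,TRUE,NA
8,20,FALSE,TRUE,TRUE,7
8,21,FALSE,FALSE,TRUE,NA
8,22,FALSE,FALSE,TRUE,NA
8,23,FALSE,TRUE,FALSE,8
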